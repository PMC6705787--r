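## Seeded simulator of multi-domain S1-like protein families.  All domains
## of all records descend from one ancestral ~70-residue domain; each site
## is independently substituted (probability d by one of the other 19
## residues), so expected identities have closed forms and the planted
## most-conserved position (the argmin of the divergence vector) is
## recoverable by the conservation statistics.

#' Default phylum-by-domain-count sampling profile
#'
#' Mirrors the observed composition of the bacterial S1 family: six-domain
#' proteins dominate (Proteobacteria, ~62% of records), four-domain
#' proteins follow (~33%, split between Firmicutes and Actinobacteria),
#' and three- (Cyanobacteria), five- (Deinococcus-Thermus), one-
#' (Tenericutes) and two-domain (Actinobacteria) proteins are rare
#' (1.9%, 1.1%, 0.8% and 0.6%).  Weights are normalized at sampling time.
#'
#' @return Data.frame with columns `phylum`, `domain_count`, `weight`.
#' @export
default_phylum_profile <- function() {
  data.frame(
    phylum = c("Tenericutes", "Actinobacteria", "Cyanobacteria",
               "Firmicutes", "Actinobacteria", "Deinococcus-Thermus",
               "Proteobacteria"),
    domain_count = c(1L, 2L, 3L, 4L, 4L, 5L, 6L),
    weight = c(0.008, 0.006, 0.019, 0.165, 0.165, 0.011, 0.620),
    stringsAsFactors = FALSE
  )
}

#' Default per-position divergence vector
#'
#' Substitution probabilities per domain position 1..6; the minimum at
#' position 3 plants central conservation as a recoverable signal.
#'
#' @return Numeric vector of length 6.
#' @export
default_divergence <- function() c(0.40, 0.35, 0.15, 0.20, 0.30, 0.40)

#' Simulation configuration
#'
#' @param n_records Number of records to generate.
#' @param seed Integer RNG seed; the whole simulation is reproducible under
#'   it (byte-identical written outputs).
#' @param ancestral_length Length of the ancestral domain (residues).
#' @param linker_length Length of the random inter-domain linkers.
#' @param phylum_profile Data.frame (`phylum`, `domain_count`, `weight`)
#'   sampled per record; see [default_phylum_profile()].
#' @param divergence Per-position substitution probabilities (length >= the
#'   largest domain count in the profile); see [default_divergence()].
#' @param contamination Named rates in \[0, 1\] for records planted to
#'   violate one filter rule each: `keyword`, `gene`, `candidate`,
#'   `zero_domain`, `extra_domain`.
#' @param contamination_counts Optional named integer vector of exact
#'   contaminant counts (overrides `contamination`).
#' @param indel_rate Optional per-site insertion/deletion probability used
#'   when evolving domains (stress-testing only; 0 keeps the
#'   substitution-only model with closed-form identities).
#' @return A validated `simulation_config`.
#' @export
simulation_config <- function(n_records = 100, seed = 1,
                              ancestral_length = 70, linker_length = 10,
                              phylum_profile = default_phylum_profile(),
                              divergence = default_divergence(),
                              contamination = c(keyword = 0, gene = 0,
                                                candidate = 0,
                                                zero_domain = 0,
                                                extra_domain = 0),
                              contamination_counts = NULL,
                              indel_rate = 0) {
  rules <- c("keyword", "gene", "candidate", "zero_domain", "extra_domain")
  full <- setNames(numeric(5), rules)
  full[names(contamination)] <- contamination
  if (any(full < 0) || sum(full) > 1)
    s1_validation_error("contamination rates must be >= 0 and sum to <= 1")
  if (!is.null(contamination_counts)) {
    cc <- setNames(integer(5), rules)
    cc[names(contamination_counts)] <- as.integer(contamination_counts)
    if (sum(cc) > n_records)
      s1_validation_error("contamination_counts exceed n_records")
    contamination_counts <- cc
  }
  if (ancestral_length < 1)
    s1_validation_error("ancestral_length must be >= 1")
  if (any(divergence < 0 | divergence > 1))
    s1_validation_error("divergence probabilities must lie in [0, 1]")
  if (max(phylum_profile$domain_count) > length(divergence))
    s1_validation_error(
      "divergence vector shorter than the largest domain count in the profile")
  if (any(phylum_profile$weight < 0) || sum(phylum_profile$weight) <= 0)
    s1_validation_error("profile weights must be non-negative and not all zero")
  structure(list(n_records = as.integer(n_records), seed = as.integer(seed),
                 ancestral_length = as.integer(ancestral_length),
                 linker_length = as.integer(linker_length),
                 phylum_profile = phylum_profile, divergence = divergence,
                 contamination = full,
                 contamination_counts = contamination_counts,
                 indel_rate = indel_rate),
            class = "simulation_config")
}

random_residues <- function(n) {
  paste(sample(AA_STANDARD, n, replace = TRUE), collapse = "")
}

#' Sample a random ancestral domain
#'
#' Residues are i.i.d. uniform over the 20 standard amino acids.
#'
#' @param length Domain length (>= 1).
#' @param seed Optional seed; the caller's RNG state is preserved.
#' @return An amino-acid string.
#' @export
sample_ancestral_domain <- function(length = 70, seed = NULL) {
  if (length < 1) s1_validation_error("length must be >= 1")
  with_seed(seed, random_residues(length))
}

#' Evolve a domain from its ancestor
#'
#' Each site is independently replaced, with probability `d`, by a
#' uniformly chosen one of the other 19 residues, so the expected identity
#' to the ancestor is `100 * (1 - d)`.  With `indel_rate > 0`, short
#' insertions/deletions (geometric lengths, mean `1/(1 - indel_ext)`) are
#' additionally applied at each site.
#'
#' @param ancestor Ancestral amino-acid string.
#' @param d Substitution probability per site, in \[0, 1\].
#' @param seed Optional seed; the caller's RNG state is preserved.
#' @param indel_rate Per-site probability of an indel event (default 0).
#' @param indel_ext Geometric extension probability of indel length.
#' @return The evolved amino-acid string.
#' @export
evolve_domain <- function(ancestor, d, seed = NULL, indel_rate = 0,
                          indel_ext = 0.5) {
  if (d < 0 || d > 1)
    s1_validation_error("substitution probability d must lie in [0, 1]")
  with_seed(seed, {
    sites <- strsplit(ancestor, "")[[1]]
    if (!all(sites %in% AA_STANDARD))
      s1_validation_error("ancestor must use the 20 standard residues")
    hit <- runif(length(sites)) < d
    if (any(hit)) {
      # uniform over the 19 other residues: shift by 1..19 in a 20-cycle
      idx <- match(sites[hit], AA_STANDARD)
      off <- sample.int(19, sum(hit), replace = TRUE)
      sites[hit] <- AA_STANDARD[((idx - 1L + off) %% 20L) + 1L]
    }
    if (indel_rate > 0 && length(sites) > 0) {
      out <- character(0)
      for (s in sites) {
        u <- runif(1)
        if (u < indel_rate / 2) {
          # deletion: drop this site
        } else if (u < indel_rate) {
          len <- 1 + stats::rgeom(1, 1 - indel_ext)
          out <- c(out, s, strsplit(random_residues(len), "")[[1]])
        } else out <- c(out, s)
      }
      sites <- out
    }
    paste(sites, collapse = "")
  })
}

#' Assemble a multi-domain protein from domain sequences
#'
#' Concatenates the domains with random linkers of `linker_length`
#' residues between consecutive domains and returns the 1-based inclusive
#' boundary pairs, which slice the input domains back exactly.
#'
#' @param domains Character vector of domain sequences (>= 1).
#' @param linker_length Linker length in residues.
#' @param seed Optional seed for the linker residues.
#' @return List with `sequence` and `boundaries` (integer matrix with
#'   columns `start`, `end`).
#' @export
assemble_protein <- function(domains, linker_length = 10, seed = NULL) {
  if (length(domains) < 1) s1_validation_error("need at least one domain")
  with_seed(seed, {
    parts <- character(0)
    starts <- integer(length(domains)); ends <- integer(length(domains))
    pos <- 0L
    for (i in seq_along(domains)) {
      if (i > 1 && linker_length > 0) {
        parts <- c(parts, random_residues(linker_length))
        pos <- pos + linker_length
      }
      starts[i] <- pos + 1L
      pos <- pos + nchar(domains[i])
      ends[i] <- pos
      parts <- c(parts, domains[i])
    }
    list(sequence = paste(parts, collapse = ""),
         boundaries = matrix(c(starts, ends), ncol = 2,
                             dimnames = list(NULL, c("start", "end"))))
  })
}

#' Simulate a multi-domain protein family with ground truth
#'
#' Draws each record's phylum and domain count from the profile, evolves
#' every domain from a shared ancestral domain at the position-specific
#' divergence, assembles chains with random linkers, and populates the
#' annotation fields.  Contaminant records are planted so that each
#' violates exactly one selection rule (wrong protein name, wrong gene,
#' candidate taxon, zero domains, or an extra non-S1 domain flag) while
#' passing all earlier rules.
#'
#' @param cfg A [simulation_config()].
#' @return A `simulated_family`: list with `dataset` (an `s1_dataset`) and
#'   `truth` (list: `ancestor`, `divergence`, `planted_index` = argmin of
#'   the divergence vector, and a `per_record` data.frame with phylum,
#'   domain count, contaminant rule (`"none"` if clean), intended filter
#'   outcome, and realized per-domain divergence).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_records
    ancestor <- random_residues(cfg$ancestral_length)
    prof <- cfg$phylum_profile
    w <- prof$weight / sum(prof$weight)
    rules <- c("keyword", "gene", "candidate", "zero_domain", "extra_domain")
    if (!is.null(cfg$contamination_counts)) {
      lab <- rep("none", n)
      pos <- sample.int(n, sum(cfg$contamination_counts))
      lab[pos] <- rep(rules, cfg$contamination_counts)
    } else {
      p <- cfg$contamination
      lab <- sample(c("none", rules), n, replace = TRUE,
                    prob = c(1 - sum(p), p))
    }
    gene_pool <- c("rpsA", "rpsA_1", "rpsA_2")
    recs <- vector("list", n)
    truth_rows <- vector("list", n)
    for (r in seq_len(n)) {
      row <- sample.int(nrow(prof), 1, prob = w)
      phylum <- prof$phylum[row]
      k <- prof$domain_count[row]
      doms <- vapply(seq_len(k), function(i)
        evolve_domain(ancestor, cfg$divergence[i],
                      indel_rate = cfg$indel_rate), character(1))
      asm <- assemble_protein(doms, cfg$linker_length)
      realized <- vapply(seq_len(k), function(i) {
        a <- strsplit(ancestor, "")[[1]]; b <- strsplit(doms[i], "")[[1]]
        if (length(a) == length(b)) mean(a != b) else NA_real_
      }, numeric(1))
      accession <- sprintf("SYN%03d", r)
      protein_name <- "30S ribosomal protein S1"
      gene_name <- sample(gene_pool, 1, prob = c(0.8, 0.1, 0.1))
      lineage <- c("Bacteria", phylum, paste0(phylum, " class"),
                   sprintf("Synthetibacter sp. %03d", r))
      has_extra <- FALSE
      boundaries <- asm$boundaries
      switch(lab[r],
        keyword = { protein_name <- "50S ribosomal protein L1" },
        gene = { gene_name <- "rpsB" },
        candidate = { lineage[3] <- "Candidatus Pelagibacter" },
        zero_domain = { boundaries <- empty_boundaries() },
        extra_domain = { has_extra <- TRUE })
      recs[[r]] <- data.frame(
        accession = accession, protein_name = protein_name,
        gene_name = gene_name, phylum = phylum, sequence = asm$sequence,
        has_extra_domains = has_extra,
        lineage = I(list(lineage)), boundaries = I(list(boundaries)),
        stringsAsFactors = FALSE)
      truth_rows[[r]] <- data.frame(
        accession = accession, phylum = phylum, domain_count = k,
        contaminant = lab[r], intended_kept = lab[r] == "none",
        realized_divergence = I(list(realized)), stringsAsFactors = FALSE)
    }
    ds <- s1_dataset(do.call(rbind, recs),
                     provenance = sprintf("simulated (seed %d)", cfg$seed))
    truth <- list(ancestor = ancestor, divergence = cfg$divergence,
                  planted_index = which.min(cfg$divergence),
                  per_record = do.call(rbind, truth_rows))
    structure(list(dataset = ds, truth = truth, config = cfg),
              class = "simulated_family")
  })
}

#' @export
print.simulated_family <- function(x, ...) {
  cat(sprintf(
    "<simulated_family> %d record(s), ancestral length %d, planted index %d\n",
    n_records(x$dataset), nchar(x$truth$ancestor), x$truth$planted_index))
  invisible(x)
}

#' Write a simulated family to disk
#'
#' Emits the FASTA + metadata TSV pair readable by [read_dataset()] plus a
#' ground-truth JSON (ancestor, divergence vector, planted index,
#' per-record intended filter outcome).
#'
#' @param fam A `simulated_family`.
#' @param dir Output directory (created if missing).
#' @param basename Stem for the three file names.
#' @return Invisibly, the named character vector of file paths.
#' @export
write_family <- function(fam, dir, basename = "family") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(fasta = file.path(dir, paste0(basename, ".fasta")),
             meta = file.path(dir, paste0(basename, ".tsv")),
             truth = file.path(dir, paste0(basename, "_truth.json")))
  write_dataset(fam$dataset, paths[["fasta"]], paths[["meta"]])
  tr <- fam$truth
  jsonlite::write_json(list(
    ancestor = tr$ancestor, divergence = tr$divergence,
    planted_index = tr$planted_index,
    per_record = tr$per_record[, c("accession", "phylum", "domain_count",
                                   "contaminant", "intended_kept")]
  ), paths[["truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
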