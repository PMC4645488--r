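## ---------------------------------------------------------------------------
## Synthetic genomes with planted domain architectures, duplicate families and
## gene clusters. Every downstream stage of the pipeline can be exercised,
## and scored against the returned ground-truth ledger, without any external
## database.
## ---------------------------------------------------------------------------

## Architecture vocabulary. NBS_LRR_NO_NTERM is an NBS-LRR without TIR or CC
## (classified NL downstream); DECOY carries no informative domain.
ARCHITECTURES <- c("NBS_ONLY", "CNL", "TNL", "NBS_LRR_NO_NTERM",
                   "KINASE_ONLY", "LRR_RLK", "LRR_RLP", "DECOY")

## Ideal heptad (registers a-g) used for planted coiled coils: Leu at the
## hydrophobic a/d registers, charged/small residues elsewhere.
IDEAL_HEPTAD <- "LEELKEK"

#' Planted duplicate-family specification
#'
#' @param architecture architecture label of all members (see
#'   [simulation_config()]).
#' @param n_members family size (>= 2).
#' @param target_identity_pct pairwise identity of each member to the family
#'   founder, in percent (0, 100].
#' @param co_clustered if `TRUE` the members are placed consecutively on one
#'   chromosome, `cluster_gap_bp` apart, so they form a planted gene cluster.
#' @return a `family_spec` list.
#' @export
family_spec <- function(architecture, n_members, target_identity_pct = 80,
                        co_clustered = FALSE) {
  architecture <- match.arg(architecture, ARCHITECTURES)
  stop_if_not_scalar_count(n_members, "n_members")
  if (n_members < 2) stop("a planted family needs >= 2 members", call. = FALSE)
  if (target_identity_pct <= 0 || target_identity_pct > 100)
    stop("target_identity_pct must be in (0, 100]", call. = FALSE)
  structure(list(architecture = architecture,
                 n_members = as.integer(n_members),
                 target_identity_pct = target_identity_pct,
                 co_clustered = isTRUE(co_clustered)),
            class = "family_spec")
}

## Default planted families: the 16 NBS-LRR family sizes of the curated maize
## catalog (one size-14 tandem array), plus one LRR-RLK family feeding the
## phylogeny stage. The size-14 and size-8 families are co-clustered.
#' @noRd
default_family_specs <- function() {
  sizes <- c(2, 2, 2, 3, 2, 8, 2, 2, 3, 4, 2, 2, 2, 4, 14, 2)
  specs <- lapply(seq_along(sizes), function(i) {
    family_spec("CNL", sizes[i], target_identity_pct = 80,
                co_clustered = sizes[i] >= 8)
  })
  c(specs, list(family_spec("LRR_RLK", 4, target_identity_pct = 80)))
}

#' Simulation configuration
#'
#' Defines the synthetic study conditions. The defaults emulate, at full
#' scale, the composition of the maize B73 LRR-receptor catalog: 217
#' NBS-encoding genes of which 151 are NBS-LRR (147 CNL + 4 TNL), 226
#' LRR-RLK genes, and 16 planted NBS-LRR multigene families (sizes
#' 2,2,2,3,2,8,2,2,3,4,2,2,2,4,14,2; 56 genes) at 80% planted identity.
#'
#' @param seed mandatory integer seed; the simulator has no implicit entropy
#'   source and identical configs produce byte-identical fixture files.
#' @param n_chromosomes number of chromosomes.
#' @param chromosome_length_bp length of each chromosome in bp.
#' @param architecture_counts named integer vector over the architecture
#'   vocabulary `NBS_ONLY, CNL, TNL, NBS_LRR_NO_NTERM, KINASE_ONLY, LRR_RLK,
#'   LRR_RLP, DECOY`; total number of genes of each class (family members
#'   included).
#' @param family_specs list of [family_spec()] entries; member counts are
#'   drawn from `architecture_counts`.
#' @param cluster_gap_bp start-to-start spacing of co-clustered family
#'   members (must stay within the clustering window used downstream).
#' @param min_intergene_gap_bp,max_intergene_gap_bp start-to-start spacing
#'   range between independent gene placements; the default 300 kb minimum
#'   guarantees that only planted clusters fall within a 200-kb window.
#' @param protein_length_range range of simulated protein lengths (aa).
#' @param decoy_nuisance_frac fraction of decoy genes that receive an
#'   above-threshold (nuisance) domain hit.
#' @return a `sim_config` list.
#' @export
simulation_config <- function(seed,
                              n_chromosomes = 10,
                              chromosome_length_bp = 2e8,
                              architecture_counts = c(
                                NBS_ONLY = 66, CNL = 147, TNL = 4,
                                NBS_LRR_NO_NTERM = 0, KINASE_ONLY = 74,
                                LRR_RLK = 226, LRR_RLP = 6, DECOY = 100),
                              family_specs = NULL,
                              cluster_gap_bp = 50000,
                              min_intergene_gap_bp = 300000,
                              max_intergene_gap_bp = 1000000,
                              protein_length_range = c(250, 400),
                              decoy_nuisance_frac = 0.5) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  ## the default planted families describe the default (full-scale)
  ## composition; a custom composition defaults to no planted families
  if (is.null(family_specs))
    family_specs <- if (missing(architecture_counts))
      default_family_specs() else list()
  stop_if_not_scalar_count(n_chromosomes, "n_chromosomes")
  stop_if_not_scalar_count(chromosome_length_bp, "chromosome_length_bp")
  counts <- setNames(integer(length(ARCHITECTURES)), ARCHITECTURES)
  if (length(architecture_counts)) {
    bad <- setdiff(names(architecture_counts), ARCHITECTURES)
    if (length(bad))
      stop("unknown architecture label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    if (any(architecture_counts < 0))
      stop("architecture counts must be >= 0", call. = FALSE)
    counts[names(architecture_counts)] <- as.integer(architecture_counts)
  }
  fam_need <- table(vapply(family_specs, `[[`, "", "architecture"))
  for (arch in names(fam_need)) {
    need <- sum(vapply(family_specs[vapply(family_specs, `[[`, "",
                                           "architecture") == arch],
                       `[[`, 0L, "n_members"))
    if (need > counts[[arch]])
      stop(sprintf("family specs need %d %s genes but only %d are configured",
                   need, arch, counts[[arch]]), call. = FALSE)
  }
  structure(list(seed = as.integer(seed),
                 n_chromosomes = as.integer(n_chromosomes),
                 chromosome_length_bp = as.numeric(chromosome_length_bp),
                 architecture_counts = counts,
                 family_specs = family_specs,
                 cluster_gap_bp = as.numeric(cluster_gap_bp),
                 min_intergene_gap_bp = as.numeric(min_intergene_gap_bp),
                 max_intergene_gap_bp = as.numeric(max_intergene_gap_bp),
                 protein_length_range = as.integer(protein_length_range),
                 decoy_nuisance_frac = decoy_nuisance_frac),
            class = "sim_config")
}

#' Random background protein
#'
#' Draws residues i.i.d. from the packaged background amino-acid composition.
#' Assumes the RNG state is already set by the caller.
#' @noRd
random_protein <- function(len) {
  paste(sample(names(AA_BACKGROUND), len, replace = TRUE,
               prob = AA_BACKGROUND), collapse = "")
}

#' Mutate a protein to a target global identity
#'
#' Substitution-only mutation model: exactly `round(L * (1 - target/100))`
#' positions are substituted with a different residue, so length and
#' coverage are preserved and the resulting global identity is within 2
#' percentage points of the target by construction.
#'
#' @param seq protein sequence (length >= 50).
#' @param target_identity_pct target identity in percent, in (0, 100].
#' @param seed integer seed (deterministic output per seed).
#' @return the mutated protein sequence.
#' @export
mutate_to_identity <- function(seq, target_identity_pct, seed) {
  stopifnot(is_protein_string(seq))
  L <- nchar(seq)
  if (L < 50) stop("sequence must be at least 50 residues", call. = FALSE)
  if (target_identity_pct <= 0 || target_identity_pct > 100)
    stop("target_identity_pct must be in (0, 100]", call. = FALSE)
  k <- round(L * (1 - target_identity_pct / 100))
  if (k == 0) return(seq)
  with_seed(seed, {
    pos <- sample.int(L, k)
    ch <- seq_chars(seq)
    for (i in pos) {
      alt <- setdiff(AA20, ch[i])
      if (!length(alt))
        stop("degenerate alphabet: no substitution available", call. = FALSE)
      ch[i] <- sample(alt, 1L)
    }
    paste(ch, collapse = "")
  })
}

#' Plant an ideal coiled-coil segment
#'
#' Overwrites `n_heptads` consecutive copies of an ideal heptad (Leu at the
#' hydrophobic a/d registers, E/K elsewhere) starting at `offset`; the rest
#' of the sequence is untouched.
#'
#' @param seq protein sequence.
#' @param offset 1-based start of the planted segment.
#' @param n_heptads number of heptads (0 returns the input unchanged).
#' @param heptad the 7-residue register template (a..g).
#' @return the modified sequence.
#' @export
plant_coiled_coil <- function(seq, offset, n_heptads, heptad = IDEAL_HEPTAD) {
  stopifnot(is_protein_string(seq), nchar(heptad) == 7L)
  stop_if_not_scalar_count(n_heptads, "n_heptads")
  if (n_heptads == 0L) return(seq)
  span <- 7L * n_heptads
  if (offset < 1 || offset + span - 1 > nchar(seq))
    stop("coiled-coil segment out of range", call. = FALSE)
  paste0(substr(seq, 1L, offset - 1L),
         strrep(heptad, n_heptads),
         substr(seq, offset + span, nchar(seq)))
}

## Domain-hit layout for one gene of a given architecture. Positions are
## fractions of the protein length; E-values are drawn below threshold for
## planted domains. Returns a data.frame of hits (possibly empty).
#' @noRd
plan_hits <- function(gene_id, arch, len, nuisance = FALSE) {
  hit <- function(acc, from, to) {
    data.frame(gene_id = gene_id, accession = acc,
               ali_start = as.integer(max(1, floor(from))),
               ali_end = as.integer(min(len, ceiling(to))),
               evalue = 10^(-runif(1, 5, 30)),
               stringsAsFactors = FALSE)
  }
  out <- list()
  if (arch %in% c("NBS_ONLY", "CNL", "TNL", "NBS_LRR_NO_NTERM"))
    out <- c(out, list(hit("PF00931", 0.30 * len, 0.62 * len)))
  if (arch %in% c("CNL", "TNL", "NBS_LRR_NO_NTERM"))
    out <- c(out, list(hit("PF00560", 0.68 * len, 0.78 * len),
                       hit("PF08263", 0.82 * len, 0.92 * len)))
  if (arch == "TNL")
    out <- c(out, list(hit("PF01582", 10, 80)))
  if (arch %in% c("KINASE_ONLY", "LRR_RLK"))
    out <- c(out, list(hit("PF00069", 0.72 * len, 0.95 * len)))
  if (arch %in% c("LRR_RLK", "LRR_RLP"))
    out <- c(out, list(hit("PF00560", 0.12 * len, 0.30 * len),
                       hit("PF08263", 0.34 * len, 0.50 * len)))
  if (arch == "DECOY" && nuisance) {
    h <- hit("PF99999", 0.4 * len, 0.6 * len)
    h$evalue <- 10^(-runif(1, 0, 3.5))   # always above a 1e-4 cutoff
    out <- c(out, list(h))
  }
  if (!length(out)) return(empty_hits())
  do.call(rbind, out)
}

#' @noRd
empty_hits <- function() {
  data.frame(gene_id = character(), accession = character(),
             ali_start = integer(), ali_end = integer(),
             evalue = numeric(), stringsAsFactors = FALSE)
}

#' @noRd
empty_genes <- function() {
  data.frame(gene_id = character(), chromosome = character(),
             start = numeric(), end = numeric(), protein = character(),
             signal_end = numeric(), tm_start = numeric(), tm_end = numeric(),
             kinase_type = character(), stringsAsFactors = FALSE)
}

#' Simulate a genome with planted LRR-receptor gene content
#'
#' Generates protein sequences, gene coordinates, a matching domain-hit
#' table, and a ground-truth ledger. Family members are derived from a
#' founder by substitution-only mutation to the planted identity (coiled
#' coils are re-planted so CNL members keep a detectable CC). Co-clustered
#' families are placed consecutively within the cluster gap; all other
#' placements are separated by at least `min_intergene_gap_bp`.
#'
#' @param config a [simulation_config()].
#' @return a list with elements `genes` (gene records: id, chromosome,
#'   1-based inclusive start/end, protein, annotation columns), `hits`
#'   (domain-hit table), and `truth` (ledger with `genes`, `families`,
#'   `clusters`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_genome_impl(config))
}

#' @noRd
simulate_genome_impl <- function(config) {
  counts <- config$architecture_counts
  total <- sum(counts)
  if (total == 0L) {
    return(list(genes = empty_genes(), hits = empty_hits(),
                truth = list(
                  genes = data.frame(gene_id = character(),
                                     architecture = character(),
                                     family_id = character(),
                                     cluster_id = character(),
                                     stringsAsFactors = FALSE),
                  families = data.frame(family_id = character(),
                                        architecture = character(),
                                        target_identity_pct = numeric(),
                                        members = character(),
                                        stringsAsFactors = FALSE),
                  clusters = data.frame(cluster_id = character(),
                                        chromosome = character(),
                                        members = character(),
                                        stringsAsFactors = FALSE))))
  }

  ## --- assign ids and architectures -------------------------------------
  gene_id <- sprintf("g%04d", seq_len(total))
  arch <- rep(names(counts), counts)
  plan <- data.frame(gene_id = gene_id, architecture = arch,
                     family_id = NA_character_, stringsAsFactors = FALSE)

  ## --- allocate family members within each architecture ------------------
  specs <- config$family_specs
  fam_ids <- sprintf("F%02d", seq_along(specs))
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    free <- which(plan$architecture == s$architecture & is.na(plan$family_id))
    take <- free[seq_len(s$n_members)]
    plan$family_id[take] <- fam_ids[i]
  }

  ## --- sequences ---------------------------------------------------------
  lens <- sample(config$protein_length_range[1]:config$protein_length_range[2],
                 total, replace = TRUE)
  prot <- character(total)
  cc_heptads <- 6L
  cc_offset <- 3L
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    idx <- which(plan$family_id == fam_ids[i])
    founder_len <- lens[idx[1]]
    lens[idx] <- founder_len                    # substitution-only model
    founder <- random_protein(founder_len)
    if (s$architecture == "CNL")
      founder <- plant_coiled_coil(founder, cc_offset, cc_heptads)
    prot[idx[1]] <- founder
    for (j in idx[-1]) {
      m <- mutate_to_identity(founder, s$target_identity_pct,
                              seed = sample.int(.Machine$integer.max, 1L))
      if (s$architecture == "CNL")
        m <- plant_coiled_coil(m, cc_offset, cc_heptads)
      prot[j] <- m
    }
  }
  singles <- which(is.na(plan$family_id))
  for (i in singles) {
    p <- random_protein(lens[i])
    if (plan$architecture[i] == "CNL")
      p <- plant_coiled_coil(p, cc_offset, cc_heptads)
    prot[i] <- p
  }

  ## --- domain hits and annotations ---------------------------------------
  nuis <- runif(total) < config$decoy_nuisance_frac
  hits <- do.call(rbind, lapply(seq_len(total), function(i) {
    plan_hits(plan$gene_id[i], plan$architecture[i], lens[i], nuis[i])
  }))
  rownames(hits) <- NULL

  signal_end <- ifelse(plan$architecture %in% c("LRR_RLK", "LRR_RLP"),
                       22, NA_real_)
  tm_start <- ifelse(plan$architecture %in% c("LRR_RLK", "LRR_RLP"),
                     floor(0.58 * lens), NA_real_)
  tm_end <- ifelse(is.na(tm_start), NA_real_, tm_start + 22)
  kinase_type <- ifelse(plan$architecture %in% c("LRR_RLK", "KINASE_ONLY"),
                        ifelse(runif(total) < 0.2, "STYK", "STK"),
                        NA_character_)

  ## --- placement ---------------------------------------------------------
  co_cl <- vapply(specs, `[[`, TRUE, "co_clustered")
  unit_of <- plan$family_id
  unit_of[is.na(unit_of)] <- plan$gene_id[is.na(unit_of)]
  clustered_fams <- fam_ids[co_cl]
  ## a unit is one co-clustered family or one gene
  unit_ids <- unique(ifelse(plan$family_id %in% clustered_fams,
                            plan$family_id, plan$gene_id))
  unit_ids <- sample(unit_ids)                 # random genome order
  members_of <- function(u) {
    if (u %in% clustered_fams) plan$gene_id[which(plan$family_id == u)]
    else u
  }
  chrom_names <- paste0("chr", seq_len(config$n_chromosomes))
  if (config$n_chromosomes == 0L)
    stop("at least one chromosome is required for a non-empty genome",
         call. = FALSE)
  cursor <- setNames(rep(0, config$n_chromosomes), chrom_names)
  res_chr <- setNames(character(total), plan$gene_id)
  res_start <- setNames(numeric(total), plan$gene_id)
  res_end <- setNames(numeric(total), plan$gene_id)
  glen <- setNames(3 * lens + 2, plan$gene_id)  # CDS-scale footprint
  cluster_id <- setNames(rep(NA_character_, total), plan$gene_id)
  next_cluster <- 1L
  for (k in seq_along(unit_ids)) {
    u <- unit_ids[k]
    chr <- chrom_names[((k - 1L) %% config$n_chromosomes) + 1L]
    mem <- members_of(u)
    gap <- runif(1, config$min_intergene_gap_bp, config$max_intergene_gap_bp)
    start <- cursor[[chr]] + floor(gap)
    for (m in mem) {
      if (start + glen[[m]] - 1 > config$chromosome_length_bp)
        stop(sprintf(
          "sizing error: unit %s does not fit on %s (%.0f bp)",
          u, chr, config$chromosome_length_bp), call. = FALSE)
      res_chr[[m]] <- chr
      res_start[[m]] <- start
      res_end[[m]] <- start + glen[[m]] - 1
      start <- start + config$cluster_gap_bp
    }
    cursor[[chr]] <- res_start[[mem[length(mem)]]]
    if (length(mem) > 1L) {
      cluster_id[mem] <- sprintf("C%02d", next_cluster)
      next_cluster <- next_cluster + 1L
    }
  }

  genes <- data.frame(gene_id = plan$gene_id, chromosome = unname(res_chr),
                      start = unname(res_start), end = unname(res_end),
                      protein = prot, signal_end = signal_end,
                      tm_start = tm_start, tm_end = tm_end,
                      kinase_type = kinase_type, stringsAsFactors = FALSE)
  genes <- genes[order(match(genes$chromosome, chrom_names), genes$start,
                       genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL

  truth_genes <- data.frame(gene_id = plan$gene_id,
                            architecture = plan$architecture,
                            family_id = plan$family_id,
                            cluster_id = unname(cluster_id[plan$gene_id]),
                            stringsAsFactors = FALSE)
  fam_rows <- lapply(seq_along(specs), function(i) {
    mem <- sort(plan$gene_id[which(plan$family_id == fam_ids[i])])
    data.frame(family_id = fam_ids[i],
               architecture = specs[[i]]$architecture,
               target_identity_pct = specs[[i]]$target_identity_pct,
               members = paste(mem, collapse = ","),
               stringsAsFactors = FALSE)
  })
  families <- if (length(fam_rows)) do.call(rbind, fam_rows) else
    data.frame(family_id = character(), architecture = character(),
               target_identity_pct = numeric(), members = character(),
               stringsAsFactors = FALSE)
  cl <- truth_genes[!is.na(truth_genes$cluster_id), , drop = FALSE]
  clusters <- if (nrow(cl)) {
    do.call(rbind, lapply(split(cl, cl$cluster_id), function(d) {
      data.frame(cluster_id = d$cluster_id[1],
                 chromosome = genes$chromosome[match(d$gene_id[1],
                                                     genes$gene_id)],
                 members = paste(sort(d$gene_id), collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(cluster_id = character(), chromosome = character(),
               members = character(), stringsAsFactors = FALSE)
  }
  rownames(clusters) <- NULL

  list(genes = genes, hits = hits,
       truth = list(genes = truth_genes, families = families,
                    clusters = clusters))
}

#' Write simulator output as standard fixture files
#'
#' Writes a protein FASTA (record id = gene id), a GFF3 of `gene` features
#' (1-based inclusive coordinates; annotation columns carried as GFF3
#' attributes), an HMMER3 `--domtblout`-dialect hit table, and optionally
#' the truth ledger as TSV. All outputs are byte-deterministic.
#'
#' @param genes gene records from [simulate_genome()].
#' @param hits domain-hit table from [simulate_genome()].
#' @param out_dir output directory (created if needed).
#' @param truth optional truth ledger to write alongside.
#' @return named character vector of the written paths.
#' @export
write_fixtures <- function(genes, hits, out_dir, truth = NULL) {
  if (!nrow(genes)) stop("empty gene list", call. = FALSE)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  paths <- c(proteins = file.path(out_dir, "proteins.faa"),
             coords = file.path(out_dir, "genes.gff3"),
             domtbl = file.path(out_dir, "hits.domtbl"))
  aa <- Biostrings::AAStringSet(setNames(genes$protein, genes$gene_id))
  Biostrings::writeXStringSet(aa, paths[["proteins"]])
  write_gff3_genes(genes, paths[["coords"]])
  write_domtbl(hits, paths[["domtbl"]],
               qlen = setNames(nchar(genes$protein), genes$gene_id))
  if (!is.null(truth)) {
    paths <- c(paths, truth = file.path(out_dir, "truth_genes.tsv"),
               truth_families = file.path(out_dir, "truth_families.tsv"),
               truth_clusters = file.path(out_dir, "truth_clusters.tsv"))
    write_tsv(truth$genes, paths[["truth"]])
    write_tsv(truth$families, paths[["truth_families"]])
    write_tsv(truth$clusters, paths[["truth_clusters"]])
  }
  paths
}
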