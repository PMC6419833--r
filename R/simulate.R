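#' Random species tree for the simulated alignment panel
#'
#' A rooted binary coalescent tree (ape::rcoal) rescaled to a given
#' root-to-tip height in expected substitutions per site. Tips are
#' labelled `s01`, `s02`, ...; `s01` is the designated reference
#' species (never dropped from simulated alignments).
#'
#' @param l Number of species (default 20).
#' @param seed RNG seed.
#' @param height Root-to-tip height in expected substitutions per site
#'   (default 0.75, giving vertebrate-like divergence spread).
#' @return An `ape::phylo` tree with attribute `reference`.
#' @export
make_species_tree <- function(l = 20L, seed = 1L, height = 0.75) {
  set.seed(seed)
  tree <- ape::rcoal(l, tip.label = sprintf("s%02d", seq_len(l)))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth * height
  attr(tree, "reference") <- "s01"
  tree
}

#' Simulation configuration for a synthetic eQTL study
#'
#' Lays out a synthetic genome on one chromosome: alternating locus
#' slots carrying SNPs or genes (TSS plus 1-3 upstream promoter
#' intervals), a planted set of coevolved SNP-gene pairs, conservation
#' shape parameters, and the eQTL p-value model. The seed fully
#' determines the layout and all downstream simulation output.
#'
#' Coevolution is planted through two channels acting on a pair's two
#' regions: a shared per-branch substitution-rate multiplier vector and
#' a shared realized species-dropout pattern; non-planted regions draw
#' both independently. The sparse-correlation score responds to the
#' shared rates, while the shared dropout exercises (and is discounted
#' by) the co-zero exclusion.
#'
#' @param seed Master seed.
#' @param l Species count.
#' @param genome_length Reference genome length in bases.
#' @param n_snps,n_genes Locus counts.
#' @param n_planted_pairs Number of planted coevolved SNP-gene pairs
#'   (distinct SNPs and genes).
#' @param matrix_flank Half-width of the alignment window around each
#'   locus used for similarity matrices (interval size is tunable).
#' @param dropout_prob Per-species, per-region probability that the
#'   species' alignment is missing in that region. Scalar or named
#'   vector by species.
#' @param background_dropout Same, for inter-locus background blocks.
#' @param rate_shape Shape of the Gamma(shape, shape) per-branch rate
#'   multipliers (mean 1; smaller shape = more rate heterogeneity and
#'   stronger plantable signal).
#' @param region_rate Overall rate multiplier for locus regions.
#' @param background_block Maximum background block length.
#' @param hc_fraction Fraction of SNPs (and of genes) given the
#'   high-conservation track shape.
#' @param noise_sd Baseline conservation-score noise sd (PhyloP-like).
#' @param snp_bump Height of the conserved flank bump at HC SNPs.
#' @param snp_dip Score at the HC SNP locus itself (negative =
#'   accelerated).
#' @param bump_width Half-width of the SNP flank bump in bases.
#' @param tss_ramp Asymptotic height of the HC TSS conservation ramp.
#' @param ramp_width Width over which the TSS ramp rises.
#' @param cis_window Maximum SNP-TSS distance for a cis pair.
#' @param true_fraction Base probability that a pair is a true eQTL.
#' @param planted_true_factor Multiplier on `true_fraction` for planted
#'   coevolved pairs (so high-score pairs are enriched for true eQTLs).
#' @param true_p_shape Shape1 of the Beta(shape1, 1) small-p
#'   distribution for true pairs.
#' @return A list of class `sim_config` with the parameters plus the
#'   generated `snps`, `genes` (stranded TSS loci), `promoters` (list
#'   per gene), and `planted_pairs`.
#' @export
sim_config <- function(seed = 1L, l = 20L, genome_length = 200000L,
                       n_snps = 200L, n_genes = 40L, n_planted_pairs = 20L,
                       matrix_flank = 100L,
                       dropout_prob = 0.3, background_dropout = 0.05,
                       rate_shape = 0.35, region_rate = 1,
                       background_block = 2000L,
                       hc_fraction = 0.5, noise_sd = 0.5,
                       snp_bump = 2, snp_dip = -1.5, bump_width = 200L,
                       tss_ramp = 2, ramp_width = 400L,
                       cis_window = 1000000L,
                       true_fraction = 0.05, planted_true_factor = 5,
                       true_p_shape = 0.1) {
  stopifnot(hc_fraction >= 0, hc_fraction <= 1,
            true_fraction >= 0, true_fraction <= 1,
            all(dropout_prob >= 0), all(dropout_prob <= 1),
            background_dropout >= 0, background_dropout <= 1)
  n_loci <- n_snps + n_genes
  slot <- (genome_length %/% (n_loci + 1L))
  f <- matrix_flank
  if (slot < 702L + f) {
    stop("config error: genome too short for the requested locus count and flank")
  }
  set.seed(seed)
  gene_slots <- sort(sample.int(n_loci, n_genes))
  slot_start <- slot * seq_len(n_loci)
  is_gene <- seq_len(n_loci) %in% gene_slots
  chrom <- "chr1"

  snp_pos <- slot_start[!is_gene] + 450L
  snps <- genomic_intervals(chrom, snp_pos, snp_pos + 1L, "*",
                            sprintf("snp_%03d", seq_len(n_snps)))
  snps$hc <- seq_len(n_snps) %in% sample.int(n_snps, round(hc_fraction * n_snps))

  tss_pos <- slot_start[is_gene] + 700L
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  genes <- genomic_intervals(chrom, tss_pos, tss_pos + 1L, strand,
                             sprintf("gene_%03d", seq_len(n_genes)))
  genes$hc <- seq_len(n_genes) %in% sample.int(n_genes, round(hc_fraction * n_genes))

  n_prom <- sample(1:3, n_genes, replace = TRUE)
  promoters <- lapply(seq_len(n_genes), function(g) {
    centres <- tss_pos[g] - (2L * f + 6L) * seq_len(n_prom[g])
    genomic_intervals(chrom, centres - f, centres + f + 1L, genes$strand[g],
                      sprintf("%s_prom%d", genes$name[g], seq_len(n_prom[g])))
  })
  names(promoters) <- genes$name

  planted <- data.frame(
    snp_id = sample(snps$name, n_planted_pairs),
    gene_id = sample(genes$name, n_planted_pairs),
    pair_id = sprintf("pair_%03d", seq_len(n_planted_pairs)),
    stringsAsFactors = FALSE
  )

  structure(list(
    seed = seed, l = l, genome_length = as.integer(genome_length),
    chrom = chrom,
    snps = snps, genes = genes, promoters = promoters,
    planted_pairs = planted,
    matrix_flank = as.integer(f),
    dropout_prob = dropout_prob, background_dropout = background_dropout,
    rate_shape = rate_shape, region_rate = region_rate,
    background_block = as.integer(background_block),
    hc_fraction = hc_fraction, noise_sd = noise_sd,
    snp_bump = snp_bump, snp_dip = snp_dip, bump_width = as.integer(bump_width),
    tss_ramp = tss_ramp, ramp_width = as.integer(ramp_width),
    cis_window = as.integer(cis_window),
    true_fraction = true_fraction, planted_true_factor = planted_true_factor,
    true_p_shape = true_p_shape
  ), class = "sim_config")
}

# Region table for the MSA simulator: one row per locus-anchored
# alignment region, with the evolutionary context shared by planted
# pair members.
.sim_regions <- function(config) {
  f <- config$matrix_flank
  ctx_of <- function(locus, kind) {
    hit <- if (kind == "snp") {
      match(locus, config$planted_pairs$snp_id)
    } else if (kind == "tss") {
      match(locus, config$planted_pairs$gene_id)
    } else {
      NA_integer_
    }
    if (!is.na(hit)) config$planted_pairs$pair_id[hit] else paste0("solo_", kind, "_", locus)
  }
  rows <- list()
  for (i in seq_len(nrow(config$snps))) {
    p <- config$snps$start[i]
    rows[[length(rows) + 1L]] <- data.frame(
      start = p - f, end = p + f + 1L, kind = "snp",
      locus_id = config$snps$name[i],
      context = ctx_of(config$snps$name[i], "snp"), stringsAsFactors = FALSE
    )
  }
  for (g in seq_len(nrow(config$genes))) {
    p <- config$genes$start[g]
    rows[[length(rows) + 1L]] <- data.frame(
      start = p - f, end = p + f + 1L, kind = "tss",
      locus_id = config$genes$name[g],
      context = ctx_of(config$genes$name[g], "tss"), stringsAsFactors = FALSE
    )
    proms <- config$promoters[[config$genes$name[g]]]
    for (k in seq_len(nrow(proms))) {
      rows[[length(rows) + 1L]] <- data.frame(
        start = proms$start[k], end = proms$end[k], kind = "promoter",
        locus_id = proms$name[k],
        context = paste0("solo_prom_", proms$name[k]), stringsAsFactors = FALSE
      )
    }
  }
  regions <- do.call(rbind, rows)
  regions <- regions[order(regions$start), , drop = FALSE]
  if (any(regions$start < 0L) || any(regions$end > config$genome_length)) {
    stop("config error: locus region outside genome bounds")
  }
  if (nrow(regions) > 1L && any(regions$start[-1L] < regions$end[-nrow(regions)])) {
    stop("config error: overlapping locus regions with conflicting rate multipliers")
  }
  rownames(regions) <- NULL
  regions
}

# Evolve one alignment block: JC sequences down the tree with
# per-branch rescaled edge lengths, then apply species dropout.
.evolve_block <- function(tree, panel, reference, chrom, start, width,
                          edge_mult, dropped) {
  t2 <- tree
  t2$edge.length <- t2$edge.length * edge_mult
  sim <- phangorn::simSeq(t2, l = width, type = "DNA")
  chars <- as.character(sim)
  rows <- apply(chars, 1L, paste0, collapse = "")
  keep <- setdiff(panel[!(panel %in% dropped)], reference)
  rows <- rows[c(reference, keep)]
  msa_block(chrom, start, rows)
}

#' Simulate a whole-genome multiple sequence alignment with planted
#' coevolved pairs
#'
#' Evolves a Jukes-Cantor root sequence down the species tree for every
#' locus region and background block of the configured genome. Each
#' region draws an evolutionary context: a per-branch rate-multiplier
#' vector (Gamma distributed, mean 1) and a realized species-dropout
#' pattern; members of a planted coevolved pair share one context, so
#' their similarity matrices have correlated deviations from the tree's
#' baseline. Background blocks evolve at baseline rate with their own
#' light dropout. Fully deterministic given the config seed.
#'
#' @param tree Species tree from [make_species_tree()] (tip count must
#'   equal `config$l`).
#' @param config A [sim_config()].
#' @return List: `blocks` (sorted [msa_block()]s, reference species
#'   first row), `manifest` (one row per block: coordinates, kind,
#'   locus, context, dropped species), `panel`.
#' @export
simulate_msa <- function(tree, config) {
  if (length(tree$tip.label) != config$l) stop("tree tip count does not match config$l")
  reference <- attr(tree, "reference")
  if (is.null(reference)) reference <- tree$tip.label[1L]
  panel <- tree$tip.label
  droppable <- setdiff(panel, reference)
  p_drop <- config$dropout_prob
  if (!is.null(names(p_drop))) {
    p_drop <- ifelse(droppable %in% names(p_drop), p_drop[droppable], 0)
  } else {
    p_drop <- rep(p_drop, length(droppable))
  }
  regions <- .sim_regions(config)
  n_edge <- nrow(tree$edge)

  set.seed(config$seed)
  contexts <- new.env(parent = emptyenv())
  draw_context <- function(key) {
    if (exists(key, envir = contexts, inherits = FALSE)) return(contexts[[key]])
    ctx <- list(
      mult = stats::rgamma(n_edge, shape = config$rate_shape, rate = config$rate_shape),
      dropped = droppable[stats::runif(length(droppable)) < p_drop]
    )
    contexts[[key]] <- ctx
    ctx
  }

  blocks <- list()
  manifest <- list()
  emit <- function(start, end, kind, locus_id, context, mult, dropped) {
    b <- .evolve_block(tree, panel, reference, config$chrom, start, end - start,
                       mult, dropped)
    blocks[[length(blocks) + 1L]] <<- b
    manifest[[length(manifest) + 1L]] <<- data.frame(
      start = start, end = end, kind = kind, locus_id = locus_id,
      context = context, dropped = paste(dropped, collapse = ","),
      stringsAsFactors = FALSE
    )
  }
  emit_background <- function(start, end) {
    while (start < end) {
      bend <- min(start + config$background_block, end)
      dropped <- droppable[stats::runif(length(droppable)) < config$background_dropout]
      emit(start, bend, "background", NA_character_, NA_character_,
           rep(1, n_edge), dropped)
      start <- bend
    }
  }

  cursor <- 0L
  for (i in seq_len(nrow(regions))) {
    if (regions$start[i] > cursor) emit_background(cursor, regions$start[i])
    ctx <- draw_context(regions$context[i])
    emit(regions$start[i], regions$end[i], regions$kind[i], regions$locus_id[i],
         regions$context[i], ctx$mult * config$region_rate, ctx$dropped)
    cursor <- regions$end[i]
  }
  if (cursor < config$genome_length) emit_background(cursor, config$genome_length)

  list(blocks = structure(blocks, reference = reference),
       manifest = do.call(rbind, manifest),
       panel = panel)
}

#' Simulate a PhyloP-like conservation track
#'
#' Baseline scores are Gaussian noise around 0 (a neutral rate).
#' High-conservation SNPs get a symmetric positive flank bump with a
#' negative (accelerated) score at the locus itself; high-conservation
#' TSSs get an asymmetric sigmoid ramp rising into the gene body,
#' oriented by the gene's strand. Low-conservation loci keep the
#' baseline. Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return List: `track` (a [conservation_track()] covering the whole
#'   genome), `snp_labels`, `gene_labels` (named
#'   `"high_conservation"`/`"low_conservation"` ground-truth vectors).
#' @export
simulate_conservation_track <- function(config) {
  if (any(config$snps$start < 0L) || any(config$snps$end > config$genome_length) ||
      any(config$genes$end > config$genome_length)) {
    stop("config error: loci outside genome bounds")
  }
  set.seed(config$seed + 1L)
  values <- stats::rnorm(config$genome_length, 0, config$noise_sd)

  bw <- config$bump_width
  bump_offsets <- -bw:bw
  bump <- config$snp_bump * exp(-(bump_offsets / (bw / 2.5))^2 / 2)
  dip_offsets <- -4:4
  dip <- (config$snp_dip - config$snp_bump) * exp(-(dip_offsets / 1.5)^2 / 2)
  for (i in which(config$snps$hc)) {
    p <- config$snps$start[i] + 1L  # 1-based index into values
    idx <- p + bump_offsets
    ok <- idx >= 1L & idx <= config$genome_length
    values[idx[ok]] <- values[idx[ok]] + bump[ok]
    idx <- p + dip_offsets
    ok <- idx >= 1L & idx <= config$genome_length
    values[idx[ok]] <- values[idx[ok]] + dip[ok]
  }

  rw <- config$ramp_width
  ramp_offsets <- -(2L * rw):(2L * rw)
  ramp <- config$tss_ramp / (1 + exp(-ramp_offsets / (rw / 5)))
  for (g in seq_len(nrow(config$genes))) {
    if (!config$genes$hc[g]) next
    p <- config$genes$start[g] + 1L
    offs <- if (config$genes$strand[g] == "-") -ramp_offsets else ramp_offsets
    idx <- p + offs
    ok <- idx >= 1L & idx <= config$genome_length
    values[idx[ok]] <- values[idx[ok]] + ramp[ok]
  }

  lab <- function(hc) ifelse(hc, "high_conservation", "low_conservation")
  track <- conservation_track(list(list(chrom = config$chrom, start = 0L, values = values)))
  list(
    track = track,
    snp_labels = stats::setNames(lab(config$snps$hc), config$snps$name),
    gene_labels = stats::setNames(lab(config$genes$hc), config$genes$name)
  )
}

#' Simulate a cis-eQTL hypothesis catalog with known truth
#'
#' Forms all same-chromosome SNP-TSS pairs within the cis window and
#' assigns each a truth label: true with the base probability, elevated
#' by `planted_true_factor` for planted coevolved pairs (so that, at
#' high coevolution-score thresholds, the retained set is enriched for
#' true eQTLs and beta > gamma holds by construction). Null pairs draw
#' p ~ Uniform(0, 1); true pairs draw p ~ Beta(`true_p_shape`, 1).
#' Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @param planted_pairs Planted coevolved pairs (defaults to
#'   `config$planted_pairs`).
#' @return List: `catalog` (a `hypothesis_catalog` with `distance`),
#'   `truth` (logical: true eQTL), `planted` (logical).
#' @export
simulate_eqtl_catalog <- function(config, planted_pairs = config$planted_pairs) {
  pairs <- expand.grid(snp_id = config$snps$name, gene_id = config$genes$name,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  snp_pos <- stats::setNames(config$snps$start, config$snps$name)
  tss_pos <- stats::setNames(config$genes$start, config$genes$name)
  pairs$snp_chrom <- config$chrom
  pairs$snp_pos <- unname(snp_pos[pairs$snp_id])
  pairs$gene_chrom <- config$chrom
  pairs$tss_pos <- unname(tss_pos[pairs$gene_id])
  dist <- abs(pairs$snp_pos - pairs$tss_pos)
  if (any(dist > config$cis_window)) {
    stop("config error: pair distance exceeds the cis window")
  }
  planted <- paste(pairs$snp_id, pairs$gene_id) %in%
    paste(planted_pairs$snp_id, planted_pairs$gene_id)
  p_true <- ifelse(planted,
                   pmin(1, config$true_fraction * config$planted_true_factor),
                   config$true_fraction)
  set.seed(config$seed + 2L)
  truth <- stats::runif(nrow(pairs)) < p_true
  p <- stats::runif(nrow(pairs))
  if (any(truth)) {
    p[truth] <- stats::rbeta(sum(truth), shape1 = config$true_p_shape, shape2 = 1)
  }
  pairs$nominal_p <- p
  list(catalog = hypothesis_catalog(pairs), truth = truth, planted = planted)
}

#' Simulate a complete synthetic eQTL study
#'
#' Runs the alignment, conservation-track, and eQTL-catalog simulators
#' under one config and returns everything with ground truth.
#'
#' @param config A [sim_config()].
#' @param tree Optional species tree; defaults to
#'   `make_species_tree(config$l, config$seed)`.
#' @return List: `config`, `tree`, `msa` (blocks + manifest + panel),
#'   `conservation` (track + labels), `eqtl` (catalog + truth +
#'   planted).
#' @export
simulate_eqtl_study <- function(config, tree = NULL) {
  if (is.null(tree)) tree <- make_species_tree(config$l, config$seed)
  list(
    config = config,
    tree = tree,
    msa = simulate_msa(tree, config),
    conservation = simulate_conservation_track(config),
    eqtl = simulate_eqtl_catalog(config)
  )
}

#' Write a simulated study to disk in standard formats
#'
#' Emits MAF (alignment blocks), fixedStep WIG (conservation track),
#' BED6 (SNP and TSS loci, promoter intervals), TSV (hypothesis
#' catalog) and a JSON truth manifest into a directory.
#'
#' @param study Output of [simulate_eqtl_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_eqtl_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    maf = file.path(dir, "alignment.maf"),
    wig = file.path(dir, "conservation.wig"),
    snps = file.path(dir, "snps.bed"),
    tss = file.path(dir, "tss.bed"),
    promoters = file.path(dir, "promoters.bed"),
    pairs = file.path(dir, "pairs.tsv"),
    manifest = file.path(dir, "truth.json")
  )
  write_maf(study$msa$blocks, paths[["maf"]])
  write_fixedstep_wig(study$conservation$track, paths[["wig"]])
  write_bed(study$config$snps, paths[["snps"]])
  write_bed(study$config$genes, paths[["tss"]])
  write_bed(do.call(rbind, study$config$promoters), paths[["promoters"]])
  write_pairs_table(study$eqtl$catalog, paths[["pairs"]])
  truth <- list(
    seed = study$config$seed,
    panel = study$msa$panel,
    snp_labels = as.list(study$conservation$snp_labels),
    gene_labels = as.list(study$conservation$gene_labels),
    planted_pairs = study$config$planted_pairs,
    true_pair = study$eqtl$truth,
    planted_pair = study$eqtl$planted
  )
  jsonlite::write_json(truth, paths[["manifest"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
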