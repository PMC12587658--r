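#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators with the default
#' study conditions: a human-like 41% GC background, enhancer repeats marked
#' by >= 2 embedded AP-1 motifs plus a +0.10 GC shift, log2(TPM+1) expression
#' at Normal(4, 1) with planted Spearman-correlated upstream pairs, a
#' 24 PE / 22 control two-batch cohort, and an overexpressed gene shifted by
#' +1.5 log2 units in 60% of PE and 25% of control samples.
#'
#' @param seed Integer master seed; every generator is a pure function of
#'   (config, seed).
#' @param n_chrom,chrom_length Number and length (bp) of synthetic
#'   chromosomes.
#' @param n_repeats Number of repeat elements placed (non-overlapping).
#' @param fraction_enhancer_repeats Fraction of repeats carrying the planted
#'   enhancer signal.
#' @param repeat_length Repeat element length in bp.
#' @param motif Planted motif (default the AP-1 consensus `TGACTCA`).
#' @param n_motif_copies Motif copies embedded per enhancer sequence (>= 2).
#' @param n_pos,n_neg,seq_length Training-set sizes and sequence length.
#' @param gc_background,gc_shift Background GC fraction and the elevation
#'   applied to enhancer sequences.
#' @param n_genes Number of genes with TSS and strand.
#' @param n_planted_pairs Number of (ERV, gene) pairs with an enhancer repeat
#'   placed wholly inside the gene's upstream window and correlated
#'   expression.
#' @param planted_pair_rho Target Spearman correlation of planted pairs.
#' @param window Upstream window width in bp (default 15000).
#' @param n_pe,n_control Cohort sizes (default 24 / 22).
#' @param expr_mean,expr_sd Background log2(TPM+1) distribution.
#' @param batch_shift Additive shift applied to batch 2 samples.
#' @param overexpressed_gene Gene carrying the planted PE overexpression
#'   (default: the first gene not in a planted pair).
#' @param frac_high_pe,frac_high_control Fractions of PE / control samples in
#'   which the overexpressed gene is shifted (defaults 0.60 / 0.25).
#' @param oe_shift Size of the overexpression shift in log2 units (+1.5).
#' @param decoy_peak_fraction Fraction of extra off-repeat decoy peaks in the
#'   simulated ChIP data (default 0.05).
#' @param n_de_genes,n_common_degs Gene universe and planted common-DEG count
#'   for the paired DE tables.
#' @param de_lfc_rho Target Spearman correlation of the common DEGs' log2
#'   fold-changes across the two tables.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 2L, chrom_length = 600000L,
                       n_repeats = 60L, fraction_enhancer_repeats = 0.4,
                       repeat_length = 600L,
                       motif = "TGACTCA", n_motif_copies = 2L,
                       n_pos = 200L, n_neg = 200L, seq_length = 600L,
                       gc_background = 0.41, gc_shift = 0.10,
                       n_genes = 30L, n_planted_pairs = 10L,
                       planted_pair_rho = 0.9, window = 15000L,
                       n_pe = 24L, n_control = 22L,
                       expr_mean = 4, expr_sd = 1,
                       batch_shift = 2,
                       overexpressed_gene = NULL,
                       frac_high_pe = 0.60, frac_high_control = 0.25,
                       oe_shift = 1.5,
                       decoy_peak_fraction = 0.05,
                       n_de_genes = 400L, n_common_degs = 25L,
                       de_lfc_rho = 0.9) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_chrom > 0, cfg$chrom_length > 0, cfg$n_repeats > 0,
            cfg$fraction_enhancer_repeats >= 0,
            cfg$fraction_enhancer_repeats <= 1,
            cfg$n_pos > 0, cfg$n_neg > 0, cfg$n_genes > 0,
            cfg$planted_pair_rho > 0, cfg$planted_pair_rho <= 1,
            grepl("^[ACGT]+$", cfg$motif),
            cfg$n_motif_copies >= 0)
  if (cfg$seq_length < nchar(cfg$motif))
    stop("seq_length must be >= motif length")
  if (cfg$n_pe < 3L || cfg$n_control < 3L)
    stop("need >= 3 samples per condition")
  if (cfg$n_planted_pairs > round(cfg$n_repeats * cfg$fraction_enhancer_repeats))
    stop("more planted pairs than enhancer repeats")
  structure(cfg, class = "sim_config")
}

.base_probs <- function(gc) c(A = (1 - gc) / 2, C = gc / 2,
                              G = gc / 2, T = (1 - gc) / 2)

.rand_dna_vec <- function(len, gc) {
  sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = .base_probs(gc))
}

# Embed n non-overlapping copies of motif into a character vector of bases.
.embed_motif <- function(bases, motif, n) {
  L <- length(bases); w <- nchar(motif)
  mchars <- strsplit(motif, "")[[1L]]
  placed <- integer(0)
  tries <- 0L
  while (length(placed) < n) {
    tries <- tries + 1L
    if (tries > 1000L) stop("could not place motif copies without overlap")
    s <- sample.int(L - w + 1L, 1L)
    if (all(abs(s - placed) >= w)) {
      bases[s:(s + w - 1L)] <- mchars
      placed <- c(placed, s)
    }
  }
  bases
}

# Spearman -> Pearson conversion for the Gaussian copula.
.rho_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

# Non-overlapping placement of n intervals of width len inside forbidden-free
# space on [0, chrom_length); forbidden is a 2-column matrix of taken spans.
.place_nonoverlap <- function(n, len, chrom_length, taken) {
  out <- matrix(NA_integer_, n, 2L)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (tries in seq_len(2000L)) {
      s <- sample.int(chrom_length - len, 1L) - 1L
      e <- s + len
      if (!nrow(taken) || all(e <= taken[, 1L] | s >= taken[, 2L])) {
        ok <- TRUE; break
      }
    }
    if (!ok) stop("genome too small to place requested repeats without overlap")
    out[i, ] <- c(s, e)
    taken <- rbind(taken, c(s, e))
  }
  list(placed = out, taken = taken)
}

#' Simulate a genome with repeats, genes and planted enhancer structure
#'
#' Builds `n_chrom` random chromosomes at background GC, places `n_genes`
#' genes (strand and TSS) and `n_repeats` non-overlapping repeat elements. A
#' fraction of the repeats are "enhancer" repeats: their sequence carries
#' `n_motif_copies` embedded motif copies and GC elevated by `gc_shift`; they
#' receive ERV3/MLT1-style family labels, the remainder ERV1/ERV2/other. For
#' each planted pair the enhancer repeat lies wholly inside the gene's
#' strand-aware upstream window.
#'
#' @param config A [sim_config()].
#' @return List with `genome` ([Biostrings::DNAStringSet]), `repeats`
#'   ([GenomicRanges::GRanges] with `name`, `family`, `superfamily`), `genes`
#'   (data frame `gene_id`, `chrom`, `tss`, `strand`) and `truth` (list with
#'   `enhancer_repeat_ids` and `planted_pairs`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  w <- config$window
  rl <- config$repeat_length
  n_enh <- round(config$n_repeats * config$fraction_enhancer_repeats)
  if (config$chrom_length < w + rl + 2000L)
    stop("chrom_length too small for the upstream-window geometry")

  chrom_names <- sprintf("chr%d", seq_len(config$n_chrom))
  chrom_seq <- lapply(chrom_names, function(cn)
    .rand_dna_vec(config$chrom_length, config$gc_background))
  names(chrom_seq) <- chrom_names

  # genes: spaced so upstream windows never collide, alternating chromosomes
  per_chrom <- split(seq_len(config$n_genes),
                     rep(chrom_names, length.out = config$n_genes))
  genes <- do.call(rbind, lapply(chrom_names, function(cn) {
    idx <- per_chrom[[cn]]
    if (!length(idx)) return(NULL)
    k <- length(idx)
    usable <- config$chrom_length - 2L * (w + rl)
    if (usable < k * 2L * (w + rl))
      stop("chrom_length too small for ", k, " genes with ", w, " bp windows")
    slot <- usable %/% k
    tss <- (w + rl) + (seq_len(k) - 1L) * slot +
      sample.int(max(1L, slot - 2L * (w + rl)), k, replace = TRUE)
    data.frame(gene_id = sprintf("GENE%03d", idx), chrom = cn,
               tss = as.integer(tss),
               strand = sample(c("+", "-"), k, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL

  # planted pairs: enhancer repeat wholly inside the gene's upstream window
  pair_genes <- genes[sample.int(nrow(genes), config$n_planted_pairs), ]
  taken <- lapply(chrom_names, function(cn) matrix(integer(0), 0L, 2L))
  names(taken) <- chrom_names
  rep_rows <- vector("list", config$n_repeats)
  for (i in seq_len(config$n_planted_pairs)) {
    g <- pair_genes[i, ]
    win0 <- if (g$strand == "+") c(max(0L, g$tss - w), g$tss)
            else c(g$tss, g$tss + w)
    off <- sample.int(w - rl, 1L) - 1L
    s <- win0[1L] + off; e <- s + rl
    taken[[g$chrom]] <- rbind(taken[[g$chrom]], c(s, e))
    rep_rows[[i]] <- data.frame(chrom = g$chrom, start = s, end = e,
                                stringsAsFactors = FALSE)
  }
  # remaining repeats anywhere, non-overlapping
  n_rest <- config$n_repeats - config$n_planted_pairs
  rest_chrom <- sample(chrom_names, n_rest, replace = TRUE)
  for (i in seq_len(n_rest)) {
    cn <- rest_chrom[i]
    pl <- .place_nonoverlap(1L, rl, config$chrom_length, taken[[cn]])
    taken[[cn]] <- pl$taken
    rep_rows[[config$n_planted_pairs + i]] <-
      data.frame(chrom = cn, start = pl$placed[1L, 1L],
                 end = pl$placed[1L, 2L], stringsAsFactors = FALSE)
  }
  reps <- do.call(rbind, rep_rows)
  reps$name <- sprintf("ERV%03d", seq_len(config$n_repeats))
  # the first n_enh repeats (which include all planted-pair repeats) are
  # enhancers; MLT1-style labels for them, other ERV families for the rest
  is_enh <- seq_len(config$n_repeats) <= n_enh
  mlt_fams <- c("MLT1G1", "MLT1F2", "MLT1B", "MLT2A1", "MLT1J")
  other_fams <- c("MER41D", "LTR12C", "HERVK9", "THE1B")
  reps$family <- ifelse(is_enh,
                        sample(mlt_fams, config$n_repeats, replace = TRUE),
                        sample(other_fams, config$n_repeats, replace = TRUE))
  reps$superfamily <- ifelse(is_enh, "ERV3",
                             sample(c("ERV1", "ERV2", "other"),
                                    config$n_repeats, replace = TRUE))
  reps$strand <- sample(c("+", "-"), config$n_repeats, replace = TRUE)

  # write repeat sequences into the chromosomes
  for (i in seq_len(nrow(reps))) {
    gc <- config$gc_background + if (is_enh[i]) config$gc_shift else 0
    bases <- .rand_dna_vec(rl, gc)
    if (is_enh[i])
      bases <- .embed_motif(bases, config$motif, config$n_motif_copies)
    chrom_seq[[reps$chrom[i]]][(reps$start[i] + 1L):reps$end[i]] <- bases
  }

  genome <- Biostrings::DNAStringSet(
    vapply(chrom_seq, paste0, character(1), collapse = ""))
  names(genome) <- chrom_names
  gr <- GenomicRanges::GRanges(reps$chrom,
                               IRanges::IRanges(reps$start + 1L, reps$end),
                               strand = reps$strand)
  S4Vectors::mcols(gr)$name <- reps$name
  S4Vectors::mcols(gr)$family <- reps$family
  S4Vectors::mcols(gr)$superfamily <- reps$superfamily

  truth <- list(
    enhancer_repeat_ids = reps$name[is_enh],
    planted_pairs = data.frame(erv_id = reps$name[seq_len(config$n_planted_pairs)],
                               gene_id = pair_genes$gene_id,
                               stringsAsFactors = FALSE))
  list(genome = genome, repeats = gr, genes = genes, truth = truth)
}

#' Simulate a labelled enhancer training set
#'
#' Positives are background sequences at elevated GC with `n_motif_copies`
#' embedded motif copies; negatives are i.i.d. background (motif occurrences
#' arise only by chance and are not suppressed).
#'
#' @param config A [sim_config()].
#' @return A [Biostrings::DNAStringSet] of `n_pos + n_neg` sequences with a
#'   `label` metadata column (1 = enhancer, 0 = non-enhancer).
#' @export
simulate_training_set <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  make <- function(n, gc, plant, prefix) {
    seqs <- vapply(seq_len(n), function(i) {
      bases <- .rand_dna_vec(config$seq_length, gc)
      if (plant && config$n_motif_copies > 0L)
        bases <- .embed_motif(bases, config$motif, config$n_motif_copies)
      paste0(bases, collapse = "")
    }, character(1))
    names(seqs) <- sprintf("%s%04d", prefix, seq_len(n))
    seqs
  }
  pos <- make(config$n_pos, config$gc_background + config$gc_shift,
              TRUE, "pos")
  neg <- make(config$n_neg, config$gc_background, FALSE, "neg")
  out <- Biostrings::DNAStringSet(c(pos, neg))
  S4Vectors::mcols(out)$label <-
    rep(c(1L, 0L), c(config$n_pos, config$n_neg))
  out
}

#' Simulate ChIP peaks and a coverage track over a genome
#'
#' Every enhancer repeat is covered by a peak jittered to retain >= 50%
#' reciprocal overlap with the repeat; a configurable fraction of decoy peaks
#' is placed off-repeat. The coverage track is 1 everywhere except a plateau
#' of 10 over each peak.
#'
#' @param config A [sim_config()].
#' @param genome_out Result of [simulate_genome()].
#' @return List with `peaks` (narrowPeak-style
#'   [GenomicRanges::GRanges]) and `coverage` (bedGraph-style
#'   [GenomicRanges::GRanges] with `score`).
#' @export
simulate_chip <- function(config, genome_out) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  reps <- genome_out$repeats
  enh <- reps[S4Vectors::mcols(reps)$name %in%
                genome_out$truth$enhancer_repeat_ids]
  # jitter both edges by at most 10% of the repeat length, keeping
  # reciprocal overlap >= 80% > the 50% threshold by construction
  jit <- function(n, len) sample.int(2L * (len %/% 10L) + 1L, n,
                                     replace = TRUE) - (len %/% 10L) - 1L
  len <- IRanges::width(enh)
  s <- GenomicRanges::start(enh) + jit(length(enh), len[1L])
  e <- GenomicRanges::end(enh) + jit(length(enh), len[1L])
  peaks <- GenomicRanges::GRanges(GenomicRanges::seqnames(enh),
                                  IRanges::IRanges(pmax(1L, s), e))
  n_decoy <- max(0L, round(length(enh) * config$decoy_peak_fraction /
                             (1 - config$decoy_peak_fraction)))
  if (n_decoy > 0L) {
    chrom_names <- names(genome_out$genome)
    dc <- character(0); ds <- integer(0)
    tries <- 0L
    while (length(dc) < n_decoy && tries < 5000L) {
      tries <- tries + 1L
      cn <- sample(chrom_names, 1L)
      st <- sample.int(config$chrom_length - 400L, 1L)
      cand <- GenomicRanges::GRanges(cn, IRanges::IRanges(st, st + 399L))
      if (!length(GenomicRanges::findOverlaps(cand, reps,
                                              ignore.strand = TRUE)) &&
          !length(GenomicRanges::findOverlaps(cand, peaks,
                                              ignore.strand = TRUE))) {
        dc <- c(dc, cn); ds <- c(ds, st)
      }
    }
    peaks <- suppressWarnings(
      c(peaks, GenomicRanges::GRanges(dc, IRanges::IRanges(ds, ds + 399L))))
  }
  S4Vectors::mcols(peaks)$name <- sprintf("peak%03d", seq_along(peaks))
  S4Vectors::mcols(peaks)$signal <- 10
  S4Vectors::mcols(peaks)$p_value <- 5
  S4Vectors::mcols(peaks)$q_value <- 3
  S4Vectors::mcols(peaks)$summit_offset <-
    as.integer(IRanges::width(peaks) %/% 2L)

  # flat track: background 1, plateau 10 over peaks
  cov <- lapply(names(genome_out$genome), function(cn) {
    p <- peaks[as.character(GenomicRanges::seqnames(peaks)) == cn]
    p <- GenomicRanges::reduce(p, ignore.strand = TRUE)
    p <- p[order(GenomicRanges::start(p))]
    s0 <- GenomicRanges::start(p) - 1L
    e0 <- GenomicRanges::end(p)
    bounds <- c(0L, as.vector(rbind(s0, e0)), config$chrom_length)
    starts <- bounds[-length(bounds)]
    ends <- bounds[-1L]
    vals <- rep(c(1, 10), length.out = length(starts))
    keep <- ends > starts
    data.frame(chrom = cn, start = starts[keep], end = ends[keep],
               score = vals[keep])
  })
  cov <- do.call(rbind, cov)
  coverage <- GenomicRanges::GRanges(cov$chrom,
                                     IRanges::IRanges(cov$start + 1L,
                                                      cov$end),
                                     score = cov$score)
  list(peaks = peaks, coverage = coverage)
}

#' Simulate the gene + ERV expression matrix with planted correlated pairs
#'
#' Features are all genes plus all ERV loci, on the log2(TPM+1) scale with
#' i.i.d. Normal(`expr_mean`, `expr_sd`) background. Each planted (ERV, gene)
#' pair is drawn from a bivariate Gaussian with Pearson correlation
#' `2*sin(pi*rho_s/6)` so its Spearman correlation targets
#' `planted_pair_rho`. Samples come in two conditions (PE / control), split
#' into two balanced batches with `batch_shift` added to batch 2, and the
#' overexpressed gene is shifted by `oe_shift` in the planted fractions of PE
#' and control samples.
#'
#' @param config A [sim_config()].
#' @param truth Ground-truth list from [simulate_genome()] (used for the
#'   planted pair identities); extended on return.
#' @param gene_ids,erv_ids Feature identifiers; defaults are taken from
#'   `truth$planted_pairs` plus generated fillers when omitted together with
#'   a `genome_out`.
#' @return List with `expr` (an [expr_set()]) and `truth` (the input truth
#'   extended with `pe_high_samples`, `control_high_samples` and
#'   `overexpressed_gene`).
#' @export
simulate_expression <- function(config, truth, gene_ids, erv_ids) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  n <- config$n_pe + config$n_control
  samples <- c(sprintf("PE%02d", seq_len(config$n_pe)),
               sprintf("CT%02d", seq_len(config$n_control)))
  condition <- rep(c("PE", "control"), c(config$n_pe, config$n_control))
  batch <- unlist(lapply(c(config$n_pe, config$n_control), function(k)
    rep(c(1L, 2L), length.out = k)))
  feats <- c(gene_ids, erv_ids)
  mat <- matrix(stats::rnorm(length(feats) * n, config$expr_mean,
                             config$expr_sd),
                nrow = length(feats), dimnames = list(feats, samples))
  # planted pairs: bivariate Gaussian copula on the same scale
  r <- .rho_pearson(config$planted_pair_rho)
  for (i in seq_len(nrow(truth$planted_pairs))) {
    z1 <- stats::rnorm(n); z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
    mat[truth$planted_pairs$erv_id[i], ] <-
      config$expr_mean + config$expr_sd * z1
    mat[truth$planted_pairs$gene_id[i], ] <-
      config$expr_mean + config$expr_sd * z2
  }
  # planted overexpression, condition-linked (not batch-linked)
  oe <- config$overexpressed_gene
  if (is.null(oe)) {
    free <- setdiff(gene_ids, truth$planted_pairs$gene_id)
    oe <- if (length(free)) free[1L] else gene_ids[1L]
  }
  k_pe <- round(config$frac_high_pe * config$n_pe)
  k_ct <- round(config$frac_high_control * config$n_control)
  hi_pe <- sample(samples[condition == "PE"], k_pe)
  hi_ct <- sample(samples[condition == "control"], k_ct)
  mat[oe, c(hi_pe, hi_ct)] <- mat[oe, c(hi_pe, hi_ct)] + config$oe_shift
  # additive batch effect on every feature
  mat[, batch == 2L] <- mat[, batch == 2L] + config$batch_shift
  expr <- expr_set(mat, data.frame(sample = samples, condition = condition,
                                   batch = batch, stringsAsFactors = FALSE))
  truth$pe_high_samples <- sort(hi_pe)
  truth$control_high_samples <- sort(hi_ct)
  truth$overexpressed_gene <- oe
  list(expr = expr, truth = truth)
}

#' Simulate two differential-expression tables with a planted common-DEG set
#'
#' `n_common_degs` genes pass the DEG filter (`padj < 0.05` and
#' `|log2fc| > 1`) in both tables with positively correlated fold-changes
#' (monotone transform of a Gaussian copula, so the Spearman target is
#' preserved exactly in rank space); every other gene fails at least one
#' criterion in at least one table.
#'
#' @param config A [sim_config()].
#' @return List with `table_a`, `table_b` (data frames `gene_id`, `log2fc`,
#'   `p`, `padj`) and `common_deg_ids`.
#' @export
simulate_de_tables <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 4L)
  m <- config$n_de_genes
  ids <- sprintf("DEG%04d", seq_len(m))
  common <- ids[seq_len(config$n_common_degs)]
  rest <- setdiff(ids, common)
  # a-only / b-only passers among the rest, then genes failing everywhere
  n_rest <- length(rest)
  grp <- sample(rep(c("a_only", "b_only", "none"),
                    c(round(0.1 * n_rest), round(0.1 * n_rest),
                      n_rest - 2L * round(0.1 * n_rest))))
  r <- .rho_pearson(config$de_lfc_rho)
  z1 <- stats::rnorm(config$n_common_degs)
  z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(config$n_common_degs)
  sgn <- sample(c(-1, 1), config$n_common_degs, replace = TRUE)
  lfc_a_common <- sgn * (1.05 + exp(0.5 * z1))
  lfc_b_common <- sgn * (1.05 + exp(0.5 * z2))
  make_table <- function(which) {
    lfc <- numeric(m); padj <- numeric(m)
    names(lfc) <- names(padj) <- ids
    lfc[common] <- if (which == "a") lfc_a_common else lfc_b_common
    padj[common] <- stats::runif(length(common), 0.001, 0.049)
    pass_here <- rest[grp == paste0(which, "_only")]
    fail_here <- setdiff(rest, pass_here)
    lfc[pass_here] <- sample(c(-1, 1), length(pass_here), TRUE) *
      stats::runif(length(pass_here), 1.1, 3)
    padj[pass_here] <- stats::runif(length(pass_here), 0.001, 0.049)
    # failures miss at least one criterion
    low_fc <- sample(c(TRUE, FALSE), length(fail_here), replace = TRUE)
    lfc[fail_here] <- ifelse(low_fc,
                             stats::runif(length(fail_here), -0.9, 0.9),
                             sample(c(-1, 1), length(fail_here), TRUE) *
                               stats::runif(length(fail_here), 1.1, 3))
    padj[fail_here] <- ifelse(low_fc,
                              stats::runif(length(fail_here), 0.001, 1),
                              stats::runif(length(fail_here), 0.051, 1))
    data.frame(gene_id = ids, log2fc = unname(lfc),
               p = unname(padj) * stats::runif(m, 0.2, 1),
               padj = unname(padj), stringsAsFactors = FALSE)
  }
  list(table_a = make_table("a"), table_b = make_table("b"),
       common_deg_ids = common)
}

#' Write a complete simulated input tree to disk
#'
#' Runs every generator and writes the standard-format files each pipeline
#' stage consumes, plus the ground truth as JSON.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return The ground-truth list, invisibly; files are written under `dir`.
#' @export
write_simulation <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- simulate_genome(config)
  write_fasta(g$genome, file.path(dir, "genome.fa"))
  write_bed(g$repeats, file.path(dir, "repeats.tsv"), kind = "repeat_table")
  write.table(g$genes, file.path(dir, "tss.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  train <- simulate_training_set(config)
  lab <- S4Vectors::mcols(train)$label
  write_fasta(train[lab == 1L], file.path(dir, "train_pos.fa"))
  write_fasta(train[lab == 0L], file.path(dir, "train_neg.fa"))
  chip <- simulate_chip(config, g)
  write_bed(chip$peaks, file.path(dir, "peaks.narrowPeak"),
            kind = "narrowPeak")
  write_bedgraph(chip$coverage, file.path(dir, "coverage.bedgraph"))
  ex <- simulate_expression(config, g$truth,
                            gene_ids = g$genes$gene_id,
                            erv_ids = S4Vectors::mcols(g$repeats)$name)
  write_expression(ex$expr, file.path(dir, "expr.tsv"),
                   file.path(dir, "meta.tsv"))
  de <- simulate_de_tables(config)
  write.table(de$table_a, file.path(dir, "de_a.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(de$table_b, file.path(dir, "de_b.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- ex$truth
  truth$common_deg_ids <- de$common_deg_ids
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(truth)
}
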