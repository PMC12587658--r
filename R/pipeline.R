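#' Extract repeat sequences from a genome
#'
#' @param genome A [Biostrings::DNAStringSet] of chromosomes.
#' @param repeats A [GenomicRanges::GRanges] with a `name` column.
#' @return A [Biostrings::DNAStringSet] named by repeat, plus-strand
#'   orientation.
#' @export
repeat_sequences <- function(genome, repeats) {
  chrom <- as.character(GenomicRanges::seqnames(repeats))
  stopifnot(all(chrom %in% names(genome)))
  seqs <- vapply(seq_along(repeats), function(i) {
    as.character(Biostrings::subseq(genome[[chrom[i]]],
                                    GenomicRanges::start(repeats)[i],
                                    GenomicRanges::end(repeats)[i]))
  }, character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- S4Vectors::mcols(repeats)$name
  out
}

#' Synthetic consensus-derived PWM counts
#'
#' Builds a count matrix concentrated on a consensus k-mer: the consensus
#' base receives `round(strength * total)` counts per column and the other
#' three bases share the remainder. This is a synthetic stand-in shaped like
#' a JASPAR count matrix (use [read_jaspar()] to supply a real one).
#'
#' @param motif Consensus string over `A,C,G,T` (default the AP-1 heptamer).
#' @param strength Fraction of counts on the consensus base (default 0.85).
#' @param total Column count total (default 100).
#' @return A 4 x nchar(motif) count matrix, rows `A,C,G,T`.
#' @export
consensus_pwm_counts <- function(motif = "TGACTCA", strength = 0.85,
                                 total = 100L) {
  stopifnot(grepl("^[ACGT]+$", motif), strength > 0.25, strength < 1)
  L <- nchar(motif)
  idx <- match(strsplit(motif, "")[[1L]], c("A", "C", "G", "T"))
  counts <- matrix(round(total * (1 - strength) / 3), 4L, L)
  counts[cbind(idx, seq_len(L))] <- round(total * strength)
  rownames(counts) <- c("A", "C", "G", "T")
  counts
}

.pipeline_defaults <- function() {
  list(
    seed = 1L,
    sim = unclass(sim_config()),
    cnn = unclass(cnn_config()),
    overlap = list(min_frac = 0.5),
    pairing = list(window = 15000L, rho_min = 0.5, q_max = 0.05),
    motif = list(mode = "normalized", normalized_threshold = 0.5,
                 raw_threshold = 8, pseudocount = 1, epsilon = 1e-6),
    dysregulation = list(alpha = 0.05, lfc_min = 1, ra_threshold = 1.0,
                         batch_adjust = TRUE),
    stages = list(chip = TRUE, de = TRUE, motif = TRUE,
                  dysregulation = TRUE)
  )
}

#' Validate (and default-fill) a pipeline configuration
#'
#' Reads a YAML file (or takes a list), rejects unknown keys with a
#' path-to-key diagnostic, type-checks numeric fields against the defaults
#' and fills every unset key with its default. An empty file yields the full
#' default configuration.
#'
#' @param path_or_list Path to a YAML file, or a (possibly nested) list.
#' @return A validated configuration list of class `pipeline_config`.
#' @export
validate_config <- function(path_or_list = list()) {
  user <- if (is.character(path_or_list)) {
    x <- yaml::read_yaml(path_or_list)
    if (is.null(x)) list() else x
  } else path_or_list
  defaults <- .pipeline_defaults()
  merge_level <- function(def, usr, where) {
    unknown <- setdiff(names(usr), names(def))
    if (length(unknown))
      stop("unknown configuration key '",
           paste0(where, unknown[1L]), "'")
    for (nm in names(usr)) {
      if (is.list(def[[nm]]) && !is.list(usr[[nm]]))
        stop("configuration key '", where, nm, "' must be a section")
      if (is.list(def[[nm]])) {
        def[[nm]] <- merge_level(def[[nm]], usr[[nm]], paste0(where, nm, "/"))
      } else {
        if (is.numeric(def[[nm]]) && !is.null(def[[nm]]) &&
            !is.numeric(usr[[nm]]))
          stop("configuration key '", where, nm, "' must be numeric")
        def[nm] <- list(usr[[nm]])   # keeps explicit-NULL keys in place
      }
    }
    def
  }
  cfg <- merge_level(defaults, user, "")
  if (cfg$pairing$window <= 0)
    stop("configuration key 'pairing/window' must be positive")
  if (cfg$overlap$min_frac < 0 || cfg$overlap$min_frac > 1)
    stop("configuration key 'overlap/min_frac' must lie in [0, 1]")
  cfg$sim$seed <- cfg$seed
  cfg$cnn$seed <- cfg$seed
  structure(cfg, class = "pipeline_config")
}

#' Run the full synthetic workflow
#'
#' Executes the stages in dependency order on simulated data: simulate
#' genome/training/ChIP/expression inputs, train and score the enhancer CNN,
#' intersect peaks with repeats, pair strong ERVs with upstream genes and
#' correlate expression, filter pairs by differential expression, scan
#' enhancer repeats for AP-1 motifs, and compute the PE dysregulation report.
#' Every resolved parameter and stage count lands in the returned manifest.
#'
#' @param config A `pipeline_config` from [validate_config()] (or a list /
#'   YAML path passed through it).
#' @param out_dir Optional directory; when given, stage outputs are written
#'   as standard-format files.
#' @return A manifest list with per-stage `counts`, the resolved `config`,
#'   stage results and elapsed wall time.
#' @export
run_pipeline <- function(config = validate_config(), out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  t0 <- proc.time()[["elapsed"]]
  counts <- list()
  simc <- do.call(sim_config, config$sim)

  genome_out <- simulate_genome(simc)
  counts$n_repeats <- length(genome_out$repeats)
  counts$n_genes <- nrow(genome_out$genes)

  train_set <- simulate_training_set(simc)
  cnnc <- do.call(cnn_config, config$cnn)
  enc <- encode_sequences(train_set, cnnc$input_length)
  sp <- split_train_test(enc$label, cnnc$test_fraction, cnnc$seed)
  sub_enc <- function(e, i) list(onehot = e$onehot[, , i, drop = FALSE],
                                 gc = e$gc[i], ids = e$ids[i],
                                 all_n = e$all_n[i], label = e$label[i])
  model <- train_enhancer_cnn(sub_enc(enc, sp$train), cnnc)
  test_pred <- predict(model, sub_enc(enc, sp$test))
  counts$heldout_accuracy <-
    mean((test_pred$probability >= 0.5) == (enc$label[sp$test] == 1L))

  erv_seqs <- repeat_sequences(genome_out$genome, genome_out$repeats)
  calls <- classify_enhancers(predict(model, erv_seqs),
                              cnnc$strong_threshold, cnnc$weak_threshold)
  counts$n_strong <- sum(calls$enhancer_class == "strong")
  counts$n_weak <- sum(calls$enhancer_class == "weak")
  counts$n_non <- sum(calls$enhancer_class == "non")

  chip <- NULL
  if (isTRUE(config$stages$chip)) {
    chip <- simulate_chip(simc, genome_out)
    ov <- intersect_annotations(chip$peaks, genome_out$repeats,
                                config$overlap$min_frac)
    counts$n_peak_supported_repeats <- length(unique(ov$repeat_id))
    # ERVs must be both sequence-predicted strong and ChIP-supported
    calls$enhancer_class[calls$enhancer_class == "strong" &
                           !(calls$sequence_id %in% ov$repeat_id)] <- "weak"
    counts$n_strong_supported <- sum(calls$enhancer_class == "strong")
  }

  ex <- simulate_expression(simc, genome_out$truth,
                            gene_ids = genome_out$genes$gene_id,
                            erv_ids = S4Vectors::mcols(genome_out$repeats)$name)
  truth <- ex$truth
  # correlation and dysregulation run on batch-adjusted expression: an
  # uncorrected global batch shift correlates every feature pair
  expr_use <- if (isTRUE(config$dysregulation$batch_adjust))
    batch_center(ex$expr)$expr else ex$expr
  cand <- find_candidate_pairs(genome_out$repeats, genome_out$genes, calls,
                               config$pairing$window)
  counts$n_candidate_pairs <- nrow(cand)
  pairs <- call_strong_pairs(pair_correlations(cand, expr_use),
                             config$pairing$rho_min, config$pairing$q_max)
  counts$n_strong_pairs <- sum(pairs$is_strong_pair)

  de <- NULL
  pairs_after_de <- NULL
  if (isTRUE(config$stages$de)) {
    de_expr <- de_wilcoxon(expr_use)
    de_genes <- filter_degs(de_expr, config$dysregulation$alpha,
                            lfc_min = 0, absolute = TRUE)$gene_id
    pairs_after_de <- pairs[pairs$is_strong_pair &
                              pairs$gene_id %in% de_genes, , drop = FALSE]
    counts$n_pairs_after_de <- nrow(pairs_after_de)
    de <- simulate_de_tables(simc)
    cd <- common_deg_correlation(de$table_a, de$table_b,
                                 config$dysregulation$alpha,
                                 config$dysregulation$lfc_min)
    counts$n_common_degs <- cd$n_common
    counts$common_deg_rho <- cd$rho
  }

  motif_hits <- NULL
  if (isTRUE(config$stages$motif)) {
    pwm <- normalize_pwm(consensus_pwm_counts(simc$motif),
                         config$motif$pseudocount)
    strong_ids <- calls$sequence_id[calls$enhancer_class == "strong"]
    motif_hits <- lapply(strong_ids, function(id) {
      h <- scan_sequence(erv_seqs[[id]], pwm,
                         mode = config$motif$mode,
                         raw_threshold = config$motif$raw_threshold,
                         normalized_threshold = config$motif$normalized_threshold,
                         epsilon = config$motif$epsilon)
      sum(h$passes)
    })
    names(motif_hits) <- strong_ids
    counts$n_strong_with_ap1 <- sum(unlist(motif_hits) > 0)
  }

  dys <- NULL
  if (isTRUE(config$stages$dysregulation)) {
    if (!isTRUE(config$stages$de))
      stop("dysregulation stage requires the de stage to be enabled")
    ra <- relative_abundance(expr_use)
    high <- flag_high(ra, truth$overexpressed_gene,
                      config$dysregulation$ra_threshold)
    pe_samples <- expr_use$meta$sample[expr_use$meta$condition == "PE"]
    dys <- list(gene = truth$overexpressed_gene,
                N = ncol(expr_use$mat), K = length(high),
                n = length(pe_samples),
                k = sum(high %in% pe_samples))
    dys$p_value <- hypergeom_enrichment(dys$N, dys$K, dys$n, dys$k)
    counts$enrichment_p <- dys$p_value
  }

  manifest <- list(counts = counts, config = unclass(config),
                   calls = calls, pairs = pairs,
                   pairs_after_de = pairs_after_de,
                   dysregulation = dys, truth = truth,
                   elapsed_s = proc.time()[["elapsed"]] - t0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(calls, file.path(out_dir, "calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(pairs, file.path(out_dir, "pairs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(counts, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest
}
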