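# Readers and writers: psmcfa-style binned sequences, VCF + callability
# mask binning, callable masks, and result export.

.need <- function(pkg) {
  if (!requireNamespace(pkg, quietly = TRUE)) {
    stop("package '", pkg, "' is required for this operation", call. = FALSE)
  }
}

#' Read / write psmcfa-style binned sequence files
#'
#' FASTA-like text with one symbol per `b`-base window over the alphabet
#' K (heterozygous), T (homozygous), N (missing); `>` headers introduce
#' contigs, body lines wrap at 60 symbols. Contig boundaries become contig
#' breaks of the observation sequence. Round trip is lossless.
#'
#' @param path file path.
#' @param bin_size window size the symbols describe (not recorded in the
#'   file; default 100).
#' @return `read_bins()` returns an [obs_sequence()]; `write_bins()`
#'   returns `path` invisibly.
#' @export
read_bins <- function(path, bin_size = 100) {
  .need("Biostrings")
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) stop("no contigs in ", path, call. = FALSE)
  chars <- strsplit(as.character(seqs), "")
  keep <- lengths(chars) > 0
  if (!any(keep)) stop("all contigs in ", path, " are empty", call. = FALSE)
  chars <- chars[keep]
  all_sym <- unlist(chars, use.names = FALSE)
  bad <- !all_sym %in% c("K", "T", "N")
  if (any(bad)) {
    sym <- all_sym[which(bad)[1]]
    lines <- readLines(path, warn = FALSE)
    at <- which(!startsWith(lines, ">") & grepl(sym, lines, fixed = TRUE))[1]
    stop(sprintf("illegal symbol '%s' in %s at line %d", sym, path, at),
         call. = FALSE)
  }
  seg_starts <- cumsum(c(1L, utils::head(lengths(chars), -1L)))
  obs_sequence(all_sym, bin_size = bin_size, seg_starts = seg_starts,
               contig_names = names(chars))
}

#' @rdname read_bins
#' @param obs an [obs_sequence()].
#' @export
write_bins <- function(obs, path) {
  stopifnot(inherits(obs, "obs_sequence"))
  sym <- symbols_as_character(obs)
  starts <- obs$seg_starts
  ends <- c(starts[-1L] - 1L, length(sym))
  nms <- obs$contig_names
  if (is.null(nms)) nms <- paste0("contig_", seq_along(starts))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(starts)) {
    writeLines(paste0(">", nms[i]), con)
    s <- sym[seq.int(starts[i], ends[i])]
    if (length(s)) {
      wrapped <- vapply(
        split(s, (seq_along(s) - 1L) %/% 60L),
        paste0, "", collapse = ""
      )
      writeLines(wrapped, con)
    }
  }
  invisible(path)
}

#' Read a BED callability mask
#'
#' @param path BED file (0-based half-open; first three columns used).
#' @return a `callability_mask`: named list of data frames (`start`, `end`)
#'   per contig, sorted and non-overlapping.
#' @export
read_bed_mask <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "numeric", "numeric",
                                         rep("NULL", max(0, .ncols(path) - 3))))
  names(df)[1:3] <- c("chrom", "start", "end")
  out <- lapply(split(df, df$chrom), function(d) {
    u <- .interval_union(d$start, d$end)
    data.frame(start = u$start, end = u$end)
  })
  structure(out, class = "callability_mask")
}

.ncols <- function(path) {
  first <- readLines(path, n = 1L)
  length(strsplit(first, "\t")[[1]])
}

#' Bin a diploid VCF plus callability mask into K/T/N windows
#'
#' Each `b`-base window `[k*b, (k+1)*b)` becomes `N` if its callable
#' fraction under the mask is below `min_callable_frac`, otherwise `K` if it
#' contains at least one callable heterozygous biallelic SNP and `T`
#' otherwise. Indels and multi-allelic records are skipped. VCF coordinates
#' are 1-based; the mask and windows are 0-based half-open.
#'
#' @param vcf_path single-sample VCF with a GT field (a multi-sample VCF
#'   needs `sample`).
#' @param mask a [read_bed_mask()] object (or `NULL`: everything callable,
#'   in which case `contig_lengths` is required).
#' @param b bin size in bases (default 100).
#' @param min_callable_frac minimum callable fraction for a window to be
#'   scored (default 0.1).
#' @param sample sample name to use from a multi-sample VCF.
#' @param contig_lengths named lengths in bases (defaults to the mask
#'   extent per contig).
#' @return an [obs_sequence()]; the per-class window counts are reported
#'   via `message()`.
#' @export
vcf_to_bins <- function(vcf_path, mask, b = 100, min_callable_frac = 0.1,
                        sample = NULL, contig_lengths = NULL) {
  .need("vcfR")
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt_all <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt_all) || ncol(gt_all) == 0) stop("VCF has no GT field")
  if (ncol(gt_all) > 1L) {
    if (is.null(sample)) {
      stop("multi-sample VCF: specify `sample`", call. = FALSE)
    }
    if (!sample %in% colnames(gt_all)) stop("sample not found in VCF")
    gt <- gt_all[, sample]
  } else {
    gt <- gt_all[, 1]
  }
  pos <- as.numeric(fix$POS)
  chrom <- fix$CHROM
  snp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) & !is.na(fix$ALT)
  het <- !is.na(gt) & gt %in% c("0/1", "1/0", "0|1", "1|0")
  if (is.null(contig_lengths)) {
    if (is.null(mask)) stop("need a mask or explicit contig_lengths")
    contig_lengths <- vapply(mask, function(d) max(d$end), 0)
  }
  contigs <- names(contig_lengths)
  all_sym <- integer(0)
  seg_starts <- integer(0)
  counts <- c(K = 0L, T = 0L, N = 0L)
  for (ct in contigs) {
    n_win <- ceiling(contig_lengths[[ct]] / b)
    callable_frac <- rep(1, n_win)
    if (!is.null(mask)) {
      callable_frac <- rep(0, n_win)
      if (ct %in% names(mask)) {
        mk <- mask[[ct]]
        for (i in seq_len(nrow(mk))) {
          w0 <- floor(mk$start[i] / b)
          w1 <- ceiling(mk$end[i] / b) - 1L
          for (w in seq.int(w0, min(w1, n_win - 1L))) {
            ov <- min(mk$end[i], (w + 1) * b) - max(mk$start[i], w * b)
            callable_frac[w + 1L] <- callable_frac[w + 1L] + max(0, ov) / b
          }
        }
      } else {
        warning("contig ", ct, " absent from mask; windows set to N")
      }
    }
    sym <- ifelse(callable_frac < min_callable_frac, 3L, 2L)
    on_ct <- which(chrom == ct & snp & het)
    if (length(on_ct)) {
      p0 <- pos[on_ct] - 1            # 0-based
      callable_site <- rep(TRUE, length(p0))
      if (!is.null(mask) && ct %in% names(mask)) {
        mk <- mask[[ct]]
        callable_site <- .positions_in_intervals(p0, mk$start, mk$end)
      }
      w <- (p0[callable_site] %/% b) + 1L
      w <- w[w >= 1 & w <= n_win]
      # masked-out windows stay N even if a variant slipped through
      hit <- unique(w)
      sym[hit] <- ifelse(sym[hit] == 3L, 3L, 1L)
    }
    seg_starts <- c(seg_starts, length(all_sym) + 1L)
    all_sym <- c(all_sym, sym)
    tb <- tabulate(sym, 3L)
    counts <- counts + c(K = tb[1], T = tb[2], N = tb[3])
  }
  message(sprintf("binned %d windows: K=%d T=%d N=%d",
                  length(all_sym), counts["K"], counts["T"], counts["N"]))
  obs_sequence(all_sym, bin_size = b, seg_starts = seg_starts,
               contig_names = contigs)
}

#' Read gene (or other feature) intervals from BED or GFF3
#'
#' @param path BED or GFF3 file (dispatch on extension via rtracklayer).
#' @param feature_type optional GFF3 feature type filter (e.g. `"gene"`).
#' @return data frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
read_gene_intervals <- function(path, feature_type = NULL) {
  .need("rtracklayer")
  gr <- rtracklayer::import(path)
  if (!is.null(feature_type) && "type" %in% names(S4Vectors::mcols(gr))) {
    gr <- gr[as.character(gr$type) %in% feature_type]
  }
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Export fitted results to plain-text files
#'
#' Writes, depending on the object: a JSON model file plus a step TSV of
#' `(time_years, N_A)` pairs for a [em_fit()] result; a bedGraph track of a
#' posterior statistic for a [decode_paths()] result (plus BED segment
#' calls at `segment_threshold`); a bedGraph of H values for an
#' [h_statistic()] track. bedGraph/BED coordinates are 0-based half-open.
#'
#' @param x a `fit_result`, `path_posterior` or `h_track`.
#' @param prefix output path prefix (files get suffixes `.model.json`,
#'   `.sizes.tsv`, `.admix.bedgraph`, `.segments.bed`, `.h.bedgraph`).
#' @inheritParams n_ref_from_theta
#' @param chrom chromosome name used in track lines.
#' @param segment_threshold posterior `P(c in {BB, AB} | X, t > T1)` above
#'   which windows are called admixed segments.
#' @return character vector of the files written, invisibly.
#' @export
export_results <- function(x, prefix, mu = 1.25e-8, b = 100, gen_time = 29,
                           chrom = "chr1", segment_threshold = 0.5) {
  files <- character(0)
  if (inherits(x, "fit_result")) {
    model <- x$model
    fj <- paste0(prefix, ".model.json")
    write_model_json(model, fj, mu = mu, b = b, gen_time = gen_time)
    sizes <- if (inherits(model, "structured_demography")) model$n_A else model$n
    bd <- model$grid$boundaries[seq_len(model$grid$n_intervals)]
    ft <- paste0(prefix, ".sizes.tsv")
    utils::write.table(
      data.frame(
        time_years = scaled_time_to_years(bd, model$theta, mu, b, gen_time),
        N_A = scaled_size_to_diploids(sizes, model$theta, mu, b)
      ),
      ft, sep = "\t", quote = FALSE, row.names = FALSE
    )
    fl <- paste0(prefix, ".loglik.tsv")
    utils::write.table(
      data.frame(iteration = seq_along(x$trajectory), loglik = x$trajectory),
      fl, sep = "\t", quote = FALSE, row.names = FALSE
    )
    files <- c(fj, ft, fl)
  } else if (inherits(x, "path_posterior")) {
    bs <- x$bin_size
    Tn <- ncol(x$marginal_c)
    padmix <- x$conditional_c["BB", ] + x$conditional_c["AB", ]
    fb <- paste0(prefix, ".admix.bedgraph")
    starts <- (seq_len(Tn) - 1L) * bs
    ok <- !is.na(padmix)
    utils::write.table(
      data.frame(chrom, starts[ok], starts[ok] + bs,
                 signif(padmix[ok], 6)),
      fb, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
    seg <- !is.na(padmix) & padmix > segment_threshold
    fs <- paste0(prefix, ".segments.bed")
    runs <- rle(seg)
    ends <- cumsum(runs$lengths)
    st <- c(0L, utils::head(ends, -1L))[runs$values]
    en <- ends[runs$values]
    utils::write.table(
      data.frame(chrom = rep(chrom, length(st)), start = st * bs,
                 end = en * bs),
      fs, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
    files <- c(fb, fs)
  } else if (inherits(x, "h_track")) {
    fh <- paste0(prefix, ".h.bedgraph")
    stride <- attr(x, "stride")
    ok <- x$callable & !is.na(x$H)
    utils::write.table(
      data.frame(chrom, x$pos[ok], x$pos[ok] + stride, signif(x$H[ok], 6)),
      fh, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
    files <- fh
  } else {
    stop("unsupported object for export_results")
  }
  invisible(files)
}
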