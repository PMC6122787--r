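## TSS assignment, TSS-to-binding-site proximity, and per-module logistic
## enrichment of transcription-factor targets.
##
## Coordinate convention throughout: BED-style 0-based half-open intervals
## [start, end).  The distance from a TSS point to an interval is 0 when the
## point lies inside, otherwise the coordinate gap to the nearer edge base
## (start - tss on the left, tss - (end - 1) on the right).

#' Strand-aware transcription start sites
#'
#' For a `+`-strand gene on `[start, end)` the TSS is `start`; for a
#' `-`-strand gene it is `end - 1` (the last base of the interval, as a
#' 0-based point).  Genes with missing strand are skipped with a warning.
#'
#' @param genes data frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand` (`"+"`/`"-"`).
#' @return data frame `gene_id`, `chrom`, `tss`.
#' @export
assign_tss <- function(genes) {
  need <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(genes)))
    stop("assign_tss: need columns ", paste(need, collapse = ", "))
  if (any(genes$start >= genes$end))
    stop("assign_tss: invalid interval(s) with start >= end")
  ok <- genes$strand %in% c("+", "-")
  if (any(!ok)) {
    warning("skipping ", sum(!ok), " gene(s) with missing/unknown strand")
    genes <- genes[ok, , drop = FALSE]
  }
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             tss = ifelse(genes$strand == "+", genes$start, genes$end - 1L),
             stringsAsFactors = FALSE)
}

#' Read a BED file of gene intervals with strand
#'
#' Expects at least 6 whitespace-separated columns
#' (chrom, start, end, name, score, strand), 0-based half-open.
#'
#' @param path file path.
#' @return data frame with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gene_bed <- function(path) {
  d <- utils::read.table(path, header = FALSE, sep = "", as.is = TRUE)
  if (ncol(d) < 6L) stop("gene BED needs 6 columns (incl. name and strand)")
  data.frame(gene_id = d[[4L]], chrom = d[[1L]], start = d[[2L]],
             end = d[[3L]], strand = d[[6L]], stringsAsFactors = FALSE)
}

#' Read a BED file of transcription-factor binding sites
#'
#' Columns: chrom, start, end, name (= TF), 0-based half-open.
#'
#' @param path file path.
#' @return data frame with `tf_name`, `chrom`, `start`, `end`.
#' @export
read_tfbs_bed <- function(path) {
  d <- utils::read.table(path, header = FALSE, sep = "", as.is = TRUE)
  if (ncol(d) < 4L) stop("TFBS BED needs 4 columns (incl. TF name)")
  data.frame(tf_name = d[[4L]], chrom = d[[1L]], start = d[[2L]],
             end = d[[3L]], stringsAsFactors = FALSE)
}

#' Read gene intervals from a GFF3 file (1-based, converted to 0-based)
#'
#' Reads `gene`-type records; the GFF3 1-based closed interval
#' `[start, end]` becomes the 0-based half-open `[start - 1, end)`.
#' The `gene_id` is taken from the `ID=` attribute.
#'
#' @param path file path.
#' @return data frame as [read_gene_bed()].
#' @export
read_gene_gff3 <- function(path) {
  d <- utils::read.table(path, header = FALSE, sep = "\t", as.is = TRUE,
                         comment.char = "#", quote = "")
  d <- d[d[[3L]] == "gene", , drop = FALSE]
  ids <- sub(".*ID=([^;]+).*", "\\1", d[[9L]])
  data.frame(gene_id = ids, chrom = d[[1L]], start = d[[4L]] - 1L,
             end = d[[5L]], strand = d[[7L]], stringsAsFactors = FALSE)
}

## Minimum point-to-interval distance for one chromosome's sorted intervals.
## tss: points; starts/ends: 0-based half-open, sorted by start.
.min_dist_sorted <- function(tss, starts, ends) {
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]
  cmax_end <- cummax(ends)
  ## candidate to the left: the max end among intervals starting at or before
  idx <- findInterval(tss, starts)
  left <- ifelse(idx == 0L, Inf,
                 pmax(0L, tss - (cmax_end[pmax(idx, 1L)] - 1L)))
  right <- ifelse(idx >= length(starts), Inf,
                  starts[pmin(idx + 1L, length(starts))] - tss)
  pmin(left, right)
}

#' Link genes to transcription factors by TSS proximity
#'
#' Builds the binary gene-by-TF target matrix: entry 1 when the gene's TSS
#' overlaps a binding site of that TF or lies within `window_bp` of one on
#' the same chromosome.  Distance is 0 inside an interval, otherwise the
#' coordinate difference to the interval's nearer edge base; the boundary
#' is inclusive (`distance <= window_bp`).
#'
#' @param tss data frame from [assign_tss()] (`gene_id`, `chrom`, `tss`).
#' @param tfbs data frame from [read_tfbs_bed()].
#' @param window_bp proximity window in base pairs (>= 0; default 2000).
#' @return integer matrix, genes x TFs, with gene ids as rownames.
#' @export
link_tfbs <- function(tss, tfbs, window_bp = 2000L) {
  stopifnot(window_bp >= 0)
  unmatched <- setdiff(unique(tss$chrom), unique(tfbs$chrom))
  if (length(unmatched) && nrow(tfbs))
    stop("chromosome name(s) in genes but not in TFBS: ",
         paste(unmatched, collapse = ", "))
  tfs <- sort(unique(tfbs$tf_name))
  out <- matrix(0L, nrow = nrow(tss), ncol = length(tfs),
                dimnames = list(tss$gene_id, tfs))
  for (tf in tfs) {
    sub <- tfbs[tfbs$tf_name == tf, , drop = FALSE]
    for (ch in unique(tss$chrom)) {
      gi <- which(tss$chrom == ch)
      si <- sub$chrom == ch
      if (!length(gi) || !any(si)) next
      d <- .min_dist_sorted(tss$tss[gi], sub$start[si], sub$end[si])
      out[gi, tf] <- as.integer(d <= window_bp)
    }
  }
  out
}

#' Per-module logistic enrichment of transcription-factor targets
#'
#' For one module, models the odds of a gene belonging to the module as a
#' function of TF target indicators.  The default (`mode =
#' "multivariable"`) enters all TF indicators jointly, so each coefficient
#' is the independent association of that TF; `mode = "univariable"` fits
#' one model per TF.  TFs with fewer than `min_targets` targets among the
#' analyzed genes are excluded (listed in attribute `"excluded"`), and TFs
#' showing separation are flagged unestimable.  Significance uses the
#' Bonferroni threshold `alpha / n_tf`.
#'
#' @param targets gene x TF 0/1 matrix from [link_tfbs()].
#' @param membership 0/1 vector (or logical) of module membership, one per
#'   row of `targets`.
#' @param n_tf number of factors in the tested family for the Bonferroni
#'   denominator; defaults to the number of TF columns supplied (the
#'   catalogue size, e.g. 161), not the post-filter count.
#' @param mode `"multivariable"` or `"univariable"`.
#' @param alpha family-wise level (default 0.05).
#' @param min_targets minimum target count per TF (default 10).
#' @return data frame per tested TF: `beta` (log-OR), `se`, `p`,
#'   `estimable`, `significant`; Bonferroni threshold in attribute
#'   `"threshold"`, excluded TFs in attribute `"excluded"`.
#' @export
module_tf_enrichment <- function(targets, membership, n_tf = ncol(targets),
                                 mode = c("multivariable", "univariable"),
                                 alpha = 0.05, min_targets = 10L) {
  mode <- match.arg(mode)
  membership <- as.integer(membership)
  stopifnot(length(membership) == nrow(targets),
            all(membership %in% c(0L, 1L)),
            all(targets %in% c(0L, 1L)))
  if (sum(membership) < 20L)
    stop("module_tf_enrichment: module has fewer than 20 member genes")
  counts <- colSums(targets)
  keep <- counts >= min_targets & counts <= nrow(targets) - min_targets
  excluded <- colnames(targets)[!keep]
  X <- targets[, keep, drop = FALSE]
  if (!ncol(X)) {
    out <- data.frame(tf = character(), beta = numeric(), se = numeric(),
                      p = numeric(), estimable = logical(),
                      significant = logical(), stringsAsFactors = FALSE)
    attr(out, "excluded") <- excluded
    attr(out, "threshold") <- alpha / n_tf
    return(out)
  }
  thr <- alpha / n_tf
  get_rows <- function(fit, tf_names) {
    sm <- summary(fit)$coefficients
    rows <- lapply(tf_names, function(tf) {
      rn <- paste0("`", tf, "`")
      hit <- if (rn %in% rownames(sm)) rn else tf
      if (!hit %in% rownames(sm))
        return(data.frame(tf = tf, beta = NA_real_, se = NA_real_,
                          p = NA_real_, estimable = FALSE))
      est <- sm[hit, ]
      estimable <- is.finite(est["Estimate"]) && abs(est["Estimate"]) <= 15 &&
        est["Std. Error"] < 100
      data.frame(tf = tf, beta = unname(est["Estimate"]),
                 se = unname(est["Std. Error"]),
                 p = unname(est["Pr(>|z|)"]), estimable = estimable)
    })
    do.call(rbind, rows)
  }
  df <- as.data.frame(X)
  df$.member <- membership
  if (mode == "multivariable") {
    rhs <- paste0("`", colnames(X), "`", collapse = " + ")
    fit <- suppressWarnings(
      stats::glm(stats::as.formula(paste0(".member ~ ", rhs)),
                 family = stats::binomial(), data = df))
    out <- get_rows(fit, colnames(X))
  } else {
    out <- do.call(rbind, lapply(colnames(X), function(tf) {
      fit <- suppressWarnings(
        stats::glm(stats::as.formula(paste0(".member ~ `", tf, "`")),
                   family = stats::binomial(), data = df))
      get_rows(fit, tf)
    }))
  }
  out$significant <- out$estimable & !is.na(out$p) & out$p < thr
  attr(out, "excluded") <- excluded
  attr(out, "threshold") <- thr
  out
}
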