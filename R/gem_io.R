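#' Gene expression matrix (GEM) container
#'
#' A GEM is a genes x samples numeric matrix with a scale marker.
#' Missing values are stored as `NA` and are excluded from every
#' downstream statistic; they are never imputed (except, explicitly,
#' inside the classifier).
#'
#' @param values numeric matrix, rownames = gene ids, colnames = sample ids.
#' @param scale `"linear"` (FPKM-like, non-negative) or `"log2"`.
#' @return an object of class `"gem"`.
#' @export
gem <- function(values, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  structure(list(values = values, scale = scale), class = "gem")
}

#' @export
print.gem <- function(x, ...) {
  cat(sprintf("GEM: %d genes x %d samples (%s scale), %.1f%% missing\n",
              nrow(x$values), ncol(x$values), x$scale,
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.gem <- function(x) dim(x$values)

#' @rdname gem
#' @param x object to test.
#' @export
is_gem <- function(x) inherits(x, "gem")

#' @rdname gem
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gem
#' @export
sample_ids <- function(x) colnames(x$values)

#' Read a GEM from a tab-delimited file
#'
#' Expected dialect: first row is the sample header (its first cell empty or
#' "gene"), first column holds gene ids, cells are numeric with `NA` or an
#' empty string for missing. Duplicated gene or sample ids and ragged rows
#' are hard errors.
#'
#' @param path file path.
#' @param scale scale marker to attach (`"linear"` or `"log2"`).
#' @return a [gem] object.
#' @export
load_gem <- function(path, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("GEM file has no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  n_col <- length(header)
  samples <- header[-1L]
  body <- fields[-1L]
  bad <- which(vapply(body, length, 1L) != n_col)
  if (length(bad))
    stop("ragged row at line ", bad[1L] + 1L, " of ", path,
         " (expected ", n_col, " fields)")
  genes <- vapply(body, `[[`, "", 1L)
  if (anyDuplicated(genes))
    stop("duplicate gene id in ", path, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (anyDuplicated(samples))
    stop("duplicate sample id in ", path, ": ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  vals <- matrix(NA_real_, length(genes), length(samples),
                 dimnames = list(genes, samples))
  for (i in seq_along(body)) {
    cell <- body[[i]][-1L]
    cell[cell == "" | cell == "NA"] <- NA
    vals[i, ] <- suppressWarnings(as.numeric(cell))
  }
  gem(vals, scale)
}

#' Write a GEM to a tab-delimited file
#'
#' @param gem a [gem] object.
#' @param path output path.
#' @export
write_gem <- function(gem, path) {
  stopifnot(is_gem(gem))
  df <- data.frame(gene = gene_ids(gem), gem$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read / write a sample annotation table
#'
#' Columns: `sample`, `condition`, plus optional numeric covariate columns.
#'
#' @param path file path.
#' @return data frame with at least `sample` and `condition` columns.
#' @export
load_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("sample", "condition") %in% names(ann)))
    stop("annotation needs `sample` and `condition` columns")
  if (anyDuplicated(ann$sample))
    stop("duplicate sample ids in annotation")
  ann
}

#' @rdname load_annotation
#' @param annot annotation data frame.
#' @export
write_annotation <- function(annot, path) {
  utils::write.table(annot, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

check_annotation <- function(gem, annot) {
  missing <- setdiff(annot$sample, sample_ids(gem))
  if (length(missing))
    stop("annotated samples absent from GEM: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  invisible(TRUE)
}

#' Merge GEMs column-wise with per-source condition labels
#'
#' All inputs must share the same gene set (any row order); the merged GEM
#' uses the first input's gene order. Each sample keeps (or receives) its
#' source annotation.
#'
#' @param gems list of [gem] objects on a common scale.
#' @param annotations list of annotation data frames, parallel to `gems`;
#'   alternatively a character vector of condition labels, one per GEM,
#'   from which annotations are built.
#' @return list with elements `gem` and `annotation`.
#' @export
merge_gems <- function(gems, annotations) {
  stopifnot(length(gems) >= 1L, all(vapply(gems, is_gem, TRUE)))
  if (is.character(annotations)) {
    stopifnot(length(annotations) == length(gems))
    annotations <- Map(function(g, cond)
      data.frame(sample = sample_ids(g), condition = cond,
                 stringsAsFactors = FALSE),
      gems, annotations)
  }
  stopifnot(length(annotations) == length(gems))
  ref <- gene_ids(gems[[1L]])
  for (i in seq_along(gems)) {
    gi <- gene_ids(gems[[i]])
    if (!setequal(gi, ref)) {
      d <- c(setdiff(ref, gi), setdiff(gi, ref))
      stop("gene sets differ between inputs; symmetric difference: ",
           paste(utils::head(d, 10L), collapse = ", "))
    }
    if (any(vapply(gems, function(g) g$scale, "") != gems[[1L]]$scale))
      stop("inputs are on different scales")
  }
  all_samples <- unlist(lapply(gems, sample_ids))
  if (anyDuplicated(all_samples))
    stop("sample id collision across inputs: ",
         paste(unique(all_samples[duplicated(all_samples)]), collapse = ", "))
  vals <- do.call(cbind, lapply(gems, function(g) g$values[ref, , drop = FALSE]))
  annot <- do.call(rbind, lapply(annotations, function(a)
    a[, union(c("sample", "condition"), names(a)), drop = FALSE]))
  rownames(annot) <- NULL
  out <- gem(vals, gems[[1L]]$scale)
  check_annotation(out, annot)
  list(gem = out, annotation = annot)
}

#' Log2-transform and quantile-normalize a linear-scale GEM
#'
#' Zeros map to missing (log2 of FPKM without pseudocount), then every
#' sample's value distribution is mapped onto the mean sorted profile
#' across samples; ties share the average of their target quantiles.
#' Samples with unequal numbers of non-missing values are matched by
#' interpolating the reference quantile function.
#'
#' @param gem a linear-scale [gem]; negative values are an error.
#' @return a log2-scale, quantile-normalized [gem].
#' @export
log2_quantile_normalize <- function(gem) {
  stopifnot(is_gem(gem))
  if (gem$scale != "linear") stop("expected a linear-scale GEM")
  v <- gem$values
  if (any(v < 0, na.rm = TRUE)) stop("negative values: input is not on linear scale")
  v[v == 0] <- NA
  lv <- log2(v)
  out <- quantile_normalize(lv)
  dimnames(out) <- dimnames(v)
  gem(out, "log2")
}

# columns are samples; NA-aware quantile normalization onto the mean
# sorted profile, ties averaged
quantile_normalize <- function(m) {
  n_obs <- colSums(!is.na(m))
  n_ref <- max(n_obs)
  if (n_ref == 0L) return(m)
  # reference quantile function on a grid of n_ref probabilities
  probs <- if (n_ref == 1L) 0.5 else seq(0, 1, length.out = n_ref)
  qs <- vapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    x <- x[!is.na(x)]
    if (!length(x)) return(rep(NA_real_, n_ref))
    stats::quantile(x, probs, names = FALSE, type = 7, na.rm = TRUE)
  }, numeric(n_ref))
  ref <- rowMeans(qs, na.rm = TRUE)
  out <- m
  for (j in seq_len(ncol(m))) {
    idx <- which(!is.na(m[, j]))
    k <- length(idx)
    if (!k) next
    p <- if (k == 1L) 0.5 else (rank(m[idx, j], ties.method = "average") - 1) / (k - 1)
    out[idx, j] <- stats::approx(probs, ref, xout = p, rule = 2)$y
  }
  out
}

#' Flag outlier samples by the Kolmogorov-Smirnov statistic
#'
#' Each sample's non-missing value distribution is compared to the pooled
#' distribution of every other sample; samples with D above `threshold`
#' are flagged. This only flags: removal is the caller's decision.
#'
#' @param gem a log2-scale [gem].
#' @param threshold KS D value above which a sample is flagged (default 0.15).
#' @return data frame with `sample`, `D`, `flagged`; samples with fewer
#'   than 2 non-missing values have `D = NA` and `flagged = TRUE`.
#' @export
ks_outlier_detect <- function(gem, threshold = 0.15) {
  stopifnot(is_gem(gem))
  if (gem$scale != "log2") stop("expected a log2-normalized GEM")
  v <- gem$values
  samples <- sample_ids(gem)
  D <- vapply(seq_along(samples), function(j) {
    x <- v[, j]; x <- x[!is.na(x)]
    if (length(x) < 2L) return(NA_real_)
    y <- v[, -j]; y <- y[!is.na(y)]
    if (length(y) < 2L) return(NA_real_)
    min(1, unname(suppressWarnings(stats::ks.test(x, y)$statistic)))
  }, 0)
  data.frame(sample = samples, D = D,
             flagged = is.na(D) | D > threshold,
             stringsAsFactors = FALSE)
}
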