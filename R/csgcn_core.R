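#' Parameters for condition-specific network construction
#'
#' Defaults are the thresholds the method prescribes: minimum cluster size
#' 30, similarity |rho| > 0.5, correlation-test alpha 0.001 with power
#' >= 0.8 (20% type-II), condition-test alpha 0.001, quantitative r^2 >
#' 0.30, differential-cluster-expression (Welch ANOVA) alpha 0.001,
#' missingness-bias t-test cut 0.1, and the analyzable log2 value window
#' [0, 15].
#'
#' @param minsim minimum |Spearman rho| for a candidate edge.
#' @param minclus minimum cluster size carried forward.
#' @param max_k maximum number of mixture components.
#' @param alpha significance threshold for correlation power and the
#'   condition proportion tests.
#' @param power minimum power of the correlation test.
#' @param r2_min minimum r-squared for quantitative condition labels.
#' @param welch_alpha differential-cluster-expression threshold (keep if
#'   both genes have p <= welch_alpha).
#' @param miss_p missingness-bias threshold (drop if p < miss_p).
#' @param low,high analyzable value window on the log2 scale.
#' @return named list of class `"csgcn_params"`.
#' @export
csgcn_params <- function(minsim = 0.5, minclus = 30, max_k = 5,
                         alpha = 0.001, power = 0.8, r2_min = 0.30,
                         welch_alpha = 0.001, miss_p = 0.1,
                         low = 0, high = 15) {
  structure(list(minsim = minsim, minclus = minclus, max_k = max_k,
                 alpha = alpha, power = power, r2_min = r2_min,
                 welch_alpha = welch_alpha, miss_p = miss_p,
                 low = low, high = high), class = "csgcn_params")
}

#' Select the analyzable samples of a gene pair
#'
#' Keeps samples where both genes are non-missing and both log2 values lie
#' in `[low, high]`.
#'
#' @param x,y aligned numeric vectors (log2 scale), names = sample ids.
#' @param low,high analyzable window.
#' @return integer indices of retained samples.
#' @export
prefilter_values <- function(x, y, low = 0, high = 15) {
  unname(which(!is.na(x) & !is.na(y) &
                 x >= low & x <= high & y >= low & y <= high))
}

#' Fit a Gaussian mixture to a gene pair's 2-D expression scatter
#'
#' Full-covariance mixtures with 1..`max_k` components are fit by EM
#' (deterministic model-based hierarchical initialisation); the component
#' count minimising BIC is selected and each sample is assigned to its
#' maximum-posterior component. Components with fewer than `min_cluster`
#' members are dropped from further testing.
#'
#' @param x,y aligned, prefiltered log2 values with sample-id names.
#' @param max_k maximum components (1-5).
#' @param min_cluster minimum members for a component to be carried forward.
#' @return `NULL` when n < `min_cluster`; otherwise a list with
#'   `k_selected`, `assignment` (named integer vector), `loglik`, `n`, and
#'   `clusters`, a list of per-component lists `(component, members, n)`
#'   restricted to components meeting the size rule.
#' @importFrom mclust Mclust mclustBIC
#' @export
fit_pair_gmm <- function(x, y, max_k = 5, min_cluster = 30) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < min_cluster) return(NULL)
  dat <- cbind(x, y)
  fit <- tryCatch(
    mclust::Mclust(dat, G = seq_len(max_k), modelNames = "VVV",
                   verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("mixture fit failed for a pair; treating as one component")
    assignment <- rep(1L, n)
    names(assignment) <- names(x)
    return(list(k_selected = 1L, assignment = assignment, loglik = NA_real_,
                n = n, clusters = list(list(component = 1L,
                                            members = names(x), n = n))))
  }
  assignment <- as.integer(fit$classification)
  names(assignment) <- names(x)
  comps <- sort(unique(assignment))
  clusters <- lapply(comps, function(k) {
    m <- names(assignment)[assignment == k]
    list(component = k, members = m, n = length(m))
  })
  clusters <- Filter(function(cl) cl$n >= min_cluster, clusters)
  list(k_selected = fit$G, assignment = assignment,
       loglik = fit$loglik, n = n, clusters = clusters)
}

#' Spearman correlation of a cluster, thresholded
#'
#' @param x,y full value vectors (named by sample).
#' @param members sample ids of the cluster.
#' @param threshold minimum |rho| (default 0.5).
#' @return list `(rho, candidate)`; `rho` is `NA` if either gene has zero
#'   variance within the cluster (never a candidate).
#' @export
cluster_spearman <- function(x, y, members, threshold = 0.5) {
  xs <- x[members]; ys <- y[members]
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0)
    return(list(rho = NA_real_, candidate = FALSE))
  rho <- stats::cor(xs, ys, method = "spearman")
  list(rho = rho, candidate = is.finite(rho) && abs(rho) > threshold)
}

#' Power of the correlation test (Fisher z approximation)
#'
#' Two-sided test of rho = 0 at level `alpha`:
#' power = Phi(|atanh(r)| * sqrt(n - 3) - z_{1 - alpha/2}).
#'
#' @param n sample size (>= 4).
#' @param r correlation under the alternative; |r| >= 1 gives power 1.
#' @param alpha significance level (default 0.001).
#' @return power in [0, 1].
#' @export
correlation_power <- function(n, r, alpha = 0.001) {
  stopifnot(n >= 4)
  if (abs(r) >= 1) return(1)
  stats::pnorm(abs(atanh(r)) * sqrt(n - 3) - stats::qnorm(1 - alpha / 2))
}

# one-sided two-sample z test of proportions, pooled variance,
# no continuity correction; H1: p1 > p2
prop_ztest_greater <- function(x1, n1, x2, n2) {
  if (n1 == 0 || n2 == 0) return(NA_real_)
  p1 <- x1 / n1; p2 <- x2 / n2
  p <- (x1 + x2) / (n1 + n2)
  se <- sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
  if (se == 0) return(1)
  stats::pnorm((p1 - p2) / se, lower.tail = FALSE)
}

#' Test whether a cluster is associated with a categorical condition
#'
#' Two one-sided proportion z-tests: (1) the fraction of in-cluster
#' samples carrying the condition label against that fraction among
#' out-of-cluster samples, and (2) the fraction of condition samples
#' captured by the cluster against the fraction of other samples in the
#' cluster. The cluster is labeled with the condition only when both
#' enrichment p-values fall below `alpha`.
#'
#' @param members in-cluster sample ids.
#' @param universe all analyzable sample ids of the pair.
#' @param annot annotation data frame.
#' @param condition condition label to test.
#' @param alpha significance threshold (default 0.001).
#' @return list `(condition, p_in_cluster, p_capture, labeled)`.
#' @export
test_condition_categorical <- function(members, universe, annot, condition,
                                       alpha = 0.001) {
  cond_of <- annot$condition[match(universe, annot$sample)]
  is_in <- universe %in% members
  is_c <- cond_of == condition
  if (!any(is_c))
    return(list(condition = condition, p_in_cluster = NA_real_,
                p_capture = NA_real_, labeled = FALSE))
  n_in <- sum(is_in); n_out <- sum(!is_in)
  p1 <- prop_ztest_greater(sum(is_in & is_c), n_in,
                           sum(!is_in & is_c), n_out)
  p2 <- prop_ztest_greater(sum(is_in & is_c), sum(is_c),
                           sum(is_in & !is_c), sum(!is_c))
  labeled <- !is.na(p1) && !is.na(p2) && p1 < alpha && p2 < alpha
  list(condition = condition, p_in_cluster = p1, p_capture = p2,
       labeled = labeled)
}

#' Test whether cluster membership tracks a quantitative covariate
#'
#' Simple linear regression of the 0/1 membership indicator on the
#' covariate over the pair's analyzable samples; labeled when r^2 exceeds
#' `r2_min` and the slope p-value falls below `alpha`.
#'
#' @param members in-cluster sample ids.
#' @param universe all analyzable sample ids.
#' @param covariate named numeric vector (by sample id).
#' @param r2_min minimum r-squared (default 0.30).
#' @param alpha slope-test threshold (default 0.001).
#' @return list `(r_square, p_reg, labeled)`.
#' @export
test_condition_quantitative <- function(members, universe, covariate,
                                        r2_min = 0.30, alpha = 0.001) {
  cv <- covariate[universe]
  ok <- !is.na(cv)
  if (sum(ok) < 3 || stats::sd(cv[ok]) == 0)
    return(list(r_square = NA_real_, p_reg = NA_real_, labeled = FALSE))
  ind <- as.numeric(universe %in% members)[ok]
  if (stats::sd(ind) == 0)
    return(list(r_square = NA_real_, p_reg = NA_real_, labeled = FALSE))
  fit <- stats::lm(ind ~ cv[ok])
  sm <- summary(fit)
  r2 <- sm$r.squared
  p <- sm$coefficients[2, 4]
  list(r_square = r2, p_reg = p, labeled = r2 > r2_min && p < alpha)
}

#' Differential-cluster-expression filter (Welch ANOVA)
#'
#' Both genes of a candidate edge must shift expression between in-cluster
#' and out-of-cluster samples (Welch one-way ANOVA p <= `alpha` for each
#' gene); otherwise the condition label may be an artifact of the mixture
#' fit rather than a real condition response.
#'
#' @param x,y full value vectors (named by sample).
#' @param members in-cluster sample ids.
#' @param universe analyzable sample ids.
#' @param alpha keep threshold (default 0.001).
#' @return list `(keep, p_a, p_b)`; undefined p (tiny group, zero
#'   variance) drops the edge.
#' @export
filter_dce <- function(x, y, members, universe, alpha = 0.001) {
  grp <- factor(ifelse(universe %in% members, "in", "out"))
  if (nlevels(droplevels(grp)) < 2 || min(table(grp)) < 2)
    return(list(keep = FALSE, p_a = NA_real_, p_b = NA_real_))
  welch_p <- function(v) {
    tryCatch(stats::oneway.test(v[universe] ~ grp, var.equal = FALSE)$p.value,
             error = function(e) NA_real_)
  }
  p_a <- welch_p(x); p_b <- welch_p(y)
  keep <- !is.na(p_a) && !is.na(p_b) && p_a <= alpha && p_b <= alpha
  list(keep = keep, p_a = p_a, p_b = p_b)
}

#' Missingness-bias filter (Student's t-test)
#'
#' For each gene of the edge, the per-sample missingness indicator is
#' compared between samples of the labeled condition and all other
#' samples; the edge is dropped when either gene's missingness is
#' condition-unbalanced (p < `p_cut`). With no missing values at all the
#' edge is trivially kept.
#'
#' @param x,y full value vectors over ALL samples (named), `NA` = missing.
#' @param annot annotation data frame.
#' @param condition the edge's labeled condition.
#' @param p_cut drop threshold (default 0.1).
#' @return list `(keep, p_a, p_b)`.
#' @export
filter_missingness_bias <- function(x, y, annot, condition, p_cut = 0.1) {
  cond_of <- annot$condition[match(names(x), annot$sample)]
  is_c <- cond_of == condition
  miss_p <- function(v) {
    ind <- as.numeric(is.na(v))
    if (sum(ind) == 0) return(NA_real_)  # no missingness: balanced
    if (stats::sd(ind[is_c]) == 0 && stats::sd(ind[!is_c]) == 0) {
      if (mean(ind[is_c]) == mean(ind[!is_c])) return(1)
      return(0)  # all-missing vs none: maximally unbalanced
    }
    tryCatch(stats::t.test(ind[is_c], ind[!is_c], var.equal = TRUE)$p.value,
             error = function(e) NA_real_)
  }
  p_a <- miss_p(x); p_b <- miss_p(y)
  drop <- (!is.na(p_a) && p_a < p_cut) || (!is.na(p_b) && p_b < p_cut)
  list(keep = !drop, p_a = p_a, p_b = p_b)
}

#' Rank a finalized edge table
#'
#' Stable sort by |similarity| descending, then r-squared descending (when
#' present), then condition-test p ascending; adds a `rank` column. No
#' edge is removed.
#'
#' @param edges edge data frame as produced by [build_csgcn].
#' @return the same rows, reordered, with `rank`.
#' @export
rank_edges <- function(edges) {
  if (!nrow(edges)) { edges$rank <- integer(0); return(edges) }
  r2 <- edges$r_square
  r2[is.na(r2)] <- -Inf
  p <- pmax(edges$p_test1, edges$p_test2)
  p[is.na(p)] <- edges$p_reg[is.na(p)]
  p[is.na(p)] <- 1
  ord <- order(-abs(edges$similarity), -r2, p)
  out <- edges[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Construct a condition-specific co-expression network
#'
#' Runs the full per-pair pipeline: value prefilter, Gaussian-mixture
#' clustering, per-cluster Spearman correlation with the similarity
#' threshold, correlation-power filter, condition association tests
#' (categorical labels from the annotation; quantitative tests for every
#' numeric annotation column), then the differential-cluster-expression
#' and missingness-bias filters, and finally ranking. One output row per
#' (gene pair, cluster, labeled condition).
#'
#' @param gem log2-normalized [gem].
#' @param annot annotation data frame (`sample`, `condition`, optional
#'   numeric covariates).
#' @param params a [csgcn_params] list.
#' @param pairs optional two-column matrix/data frame of gene-id pairs to
#'   restrict the (otherwise quadratic) enumeration; default all pairs.
#' @param genes optional gene-id subset (ignored when `pairs` given).
#' @return edge data frame (class `"csgcn_edges"`): `source`, `target`,
#'   `similarity`, `cluster_index`, `cluster_size`, `power`, `condition`,
#'   `p_test1`, `p_test2`, `r_square`, `p_reg`, `p_welch_a`, `p_welch_b`,
#'   `p_miss_a`, `p_miss_b`, `rank`.
#' @export
build_csgcn <- function(gem, annot, params = csgcn_params(),
                        pairs = NULL, genes = NULL) {
  stopifnot(is_gem(gem), inherits(params, "csgcn_params"))
  if (gem$scale != "log2") stop("expected a log2-normalized GEM")
  check_annotation(gem, annot)
  if (length(unique(annot$condition)) < 2)
    stop("need >= 2 condition labels for condition testing")
  all_genes <- gene_ids(gem)
  if (is.null(pairs)) {
    gs <- if (is.null(genes)) all_genes else intersect(genes, all_genes)
    if (length(gs) < 2) stop("fewer than 2 genes to pair")
    pairs <- t(utils::combn(gs, 2))
  } else {
    pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
    bad <- !(pairs %in% all_genes)
    if (any(bad)) stop("pair gene absent from GEM: ",
                       paste(utils::head(unique(pairs[bad]), 5L), collapse = ", "))
  }
  # lexicographic pair order for stable, deduplicated output
  flip <- pairs[, 1] > pairs[, 2]
  pairs[flip, ] <- pairs[flip, 2:1]
  pairs <- unique(pairs)
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]

  conditions <- sort(unique(annot$condition))
  covars <- names(annot)[vapply(annot, is.numeric, TRUE)]
  v <- gem$values
  rows <- vector("list", 256L); nr <- 0L

  for (i in seq_len(nrow(pairs))) {
    ga <- pairs[i, 1]; gb <- pairs[i, 2]
    x <- v[ga, ]; y <- v[gb, ]
    keep <- prefilter_values(x, y, params$low, params$high)
    if (length(keep) < params$minclus) next
    xs <- x[keep]; ys <- y[keep]
    fit <- fit_pair_gmm(xs, ys, max_k = params$max_k,
                        min_cluster = params$minclus)
    if (is.null(fit)) next
    universe <- names(xs)
    for (cl in fit$clusters) {
      cs <- cluster_spearman(xs, ys, cl$members, threshold = params$minsim)
      if (!cs$candidate) next
      pw <- correlation_power(cl$n, cs$rho, alpha = params$alpha)
      if (pw < params$power) next
      labels <- list()
      for (co in conditions) {
        tc <- test_condition_categorical(cl$members, universe, annot, co,
                                         alpha = params$alpha)
        if (tc$labeled) labels[[length(labels) + 1L]] <-
          list(condition = co, p1 = tc$p_in_cluster, p2 = tc$p_capture,
               r2 = NA_real_, p_reg = NA_real_)
      }
      for (cvn in covars) {
        cv <- stats::setNames(annot[[cvn]], annot$sample)
        tq <- test_condition_quantitative(cl$members, universe, cv,
                                          r2_min = params$r2_min,
                                          alpha = params$alpha)
        if (tq$labeled) labels[[length(labels) + 1L]] <-
          list(condition = cvn, p1 = NA_real_, p2 = NA_real_,
               r2 = tq$r_square, p_reg = tq$p_reg)
      }
      if (!length(labels)) next
      dce <- filter_dce(xs, ys, cl$members, universe,
                        alpha = params$welch_alpha)
      if (!dce$keep) next
      for (lb in labels) {
        if (lb$condition %in% conditions) {
          mb <- filter_missingness_bias(x, y, annot, lb$condition,
                                        p_cut = params$miss_p)
          if (!mb$keep) next
        } else mb <- list(p_a = NA_real_, p_b = NA_real_)
        nr <- nr + 1L
        if (nr > length(rows)) rows <- c(rows, vector("list", length(rows)))
        rows[[nr]] <- data.frame(
          source = ga, target = gb, similarity = cs$rho,
          cluster_index = cl$component, cluster_size = cl$n, power = pw,
          condition = lb$condition, p_test1 = lb$p1, p_test2 = lb$p2,
          r_square = lb$r2, p_reg = lb$p_reg,
          p_welch_a = dce$p_a, p_welch_b = dce$p_b,
          p_miss_a = mb$p_a, p_miss_b = mb$p_b,
          stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (nr) do.call(rbind, rows[seq_len(nr)]) else
    data.frame(source = character(), target = character(),
               similarity = numeric(), cluster_index = integer(),
               cluster_size = integer(), power = numeric(),
               condition = character(), p_test1 = numeric(),
               p_test2 = numeric(), r_square = numeric(),
               p_reg = numeric(), p_welch_a = numeric(),
               p_welch_b = numeric(), p_miss_a = numeric(),
               p_miss_b = numeric(), stringsAsFactors = FALSE)
  edges <- rank_edges(edges)
  class(edges) <- c("csgcn_edges", class(edges))
  edges
}

#' Write / read a ranked edge table as TSV
#'
#' @param edges edge data frame from [build_csgcn].
#' @param path file path.
#' @export
write_edges <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_edges
#' @export
load_edges <- function(path) {
  e <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("source", "target", "condition") %in% names(e)))
    stop("edge table needs source, target, condition columns")
  class(e) <- c("csgcn_edges", class(e))
  e
}
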