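#' Per-gene differential expression between two conditions
#'
#' Fold change is reported for `cond_b` relative to `cond_a` on the log2
#' scale; p-values are Benjamini-Hochberg adjusted across all tested
#' genes and a gene is a DEG when the adjusted p falls below `alpha`.
#'
#' Two test routes: `"welch"` (default) runs a Welch t-test on log2
#' values, appropriate for FPKM-scale matrices; `"nb"` fits a per-gene
#' negative-binomial GLM on (rounded) counts and reports the Wald p of
#' the condition coefficient. `"auto"` picks `"nb"` only when the matrix
#' is integer-valued on the linear scale.
#'
#' @param gem a [gem] (linear or log2 scale).
#' @param annot annotation data frame.
#' @param cond_a,cond_b condition labels (>= 3 samples each).
#' @param alpha DEG threshold on the adjusted p (default 0.001).
#' @param method `"auto"`, `"welch"` or `"nb"`.
#' @return data frame `gene`, `log2_fc`, `p`, `adj_p`, `is_deg`,
#'   `direction` (`up`/`down`/`none`); genes with a fully missing group
#'   are excluded and listed in `attr(, "excluded")`. The route used is
#'   recorded in `attr(, "method")`.
#' @export
de_test <- function(gem, annot, cond_a, cond_b, alpha = 0.001,
                    method = c("auto", "welch", "nb")) {
  method <- match.arg(method)
  stopifnot(is_gem(gem))
  check_annotation(gem, annot)
  sa <- annot$sample[annot$condition == cond_a]
  sb <- annot$sample[annot$condition == cond_b]
  if (length(sa) < 3 || length(sb) < 3)
    stop("both conditions need >= 3 samples")
  v <- gem$values
  lin <- if (gem$scale == "linear") v else 2^v
  if (method == "auto") {
    x <- lin[!is.na(lin)]
    method <- if (length(x) && all(abs(x - round(x)) < 1e-8)) "nb" else "welch"
  }
  lg <- if (gem$scale == "log2") v else suppressWarnings(log2(v))
  lg[!is.finite(lg)] <- NA

  genes <- gene_ids(gem)
  res <- lapply(genes, function(g) {
    xa <- lg[g, sa]; xb <- lg[g, sb]
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    if (length(xa) < 2 || length(xb) < 2)
      return(NULL)
    lfc <- mean(xb) - mean(xa)
    p <- if (method == "welch") {
      if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
        if (mean(xa) == mean(xb)) 1 else 0
      } else {
        tryCatch(stats::t.test(xb, xa)$p.value, error = function(e) NA_real_)
      }
    } else {
      nb_wald_p(round(lin[g, sa]), round(lin[g, sb]))
    }
    data.frame(gene = g, log2_fc = lfc, p = p, stringsAsFactors = FALSE)
  })
  keep <- !vapply(res, is.null, TRUE)
  out <- do.call(rbind, res[keep])
  if (is.null(out))
    out <- data.frame(gene = character(), log2_fc = numeric(), p = numeric())
  out$adj_p <- stats::p.adjust(out$p, method = "BH")
  out$is_deg <- !is.na(out$adj_p) & out$adj_p < alpha
  out$direction <- ifelse(!out$is_deg, "none",
                          ifelse(out$log2_fc > 0, "up", "down"))
  rownames(out) <- NULL
  attr(out, "excluded") <- genes[!keep]
  attr(out, "method") <- method
  out
}

# Wald p for the group coefficient of a per-gene NB GLM; falls back to a
# quasi-Poisson fit when the NB dispersion estimate degenerates
nb_wald_p <- function(ca, cb) {
  cnt <- c(ca, cb); grp <- factor(rep(c("a", "b"), c(length(ca), length(cb))))
  ok <- !is.na(cnt)
  if (sum(ok & grp == "a") < 2 || sum(ok & grp == "b") < 2) return(NA_real_)
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(cnt[ok] ~ grp[ok])),
    error = function(e) NULL)
  if (is.null(fit))
    fit <- tryCatch(
      suppressWarnings(stats::glm(cnt[ok] ~ grp[ok], family = stats::quasipoisson())),
      error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  cf <- summary(fit)$coefficients
  if (nrow(cf) < 2) return(NA_real_)
  cf[2, 4]
}

#' TF/TR expression-ratio shift test
#'
#' For every sample the ratio (TF + eps) / (TR + eps) is taken on the
#' linear scale, and the two condition groups are compared with the
#' classical equal-variance Student's t-test; significant when p < alpha.
#'
#' @param gem a [gem].
#' @param tf,tr gene ids (TF and its target/regulated gene).
#' @param annot annotation data frame.
#' @param cond_a,cond_b condition labels.
#' @param alpha significance threshold (default 0.001).
#' @param eps pseudocount guarding division by zero (default 0.01).
#' @return list `(tf, tr, mean_a, sd_a, mean_b, sd_b, n_a, n_b, t_stat, p,
#'   significant, ok)`; `ok = FALSE` (never significant) when fewer than 3
#'   computable ratios remain in either condition or the ratios are
#'   degenerate.
#' @export
tf_tr_ratio_test <- function(gem, tf, tr, annot, cond_a, cond_b,
                             alpha = 0.001, eps = 0.01) {
  stopifnot(is_gem(gem))
  if (!all(c(tf, tr) %in% gene_ids(gem)))
    stop("tf/tr gene absent from GEM")
  v <- gem$values
  lin <- if (gem$scale == "linear") v else 2^v
  ratio_in <- function(cond) {
    s <- annot$sample[annot$condition == cond]
    r <- (lin[tf, s] + eps) / (lin[tr, s] + eps)
    r[!is.na(r)]
  }
  ra <- ratio_in(cond_a); rb <- ratio_in(cond_b)
  base <- list(tf = tf, tr = tr,
               mean_a = mean(ra), sd_a = stats::sd(ra), n_a = length(ra),
               mean_b = mean(rb), sd_b = stats::sd(rb), n_b = length(rb))
  if (length(ra) < 3 || length(rb) < 3)
    return(c(base, list(t_stat = NA_real_, p = NA_real_,
                        significant = FALSE, ok = FALSE)))
  if (stats::sd(c(ra, rb)) == 0)
    return(c(base, list(t_stat = 0, p = 1, significant = FALSE, ok = FALSE)))
  tt <- stats::t.test(ra, rb, var.equal = TRUE)
  c(base, list(t_stat = unname(tt$statistic), p = tt$p.value,
               significant = tt$p.value < alpha, ok = TRUE))
}

#' Ratio tests for a table of regulatory edges
#'
#' @param gem,annot,cond_a,cond_b,alpha,eps as in [tf_tr_ratio_test].
#' @param grn data frame with `tf`, `target` columns.
#' @return data frame, one row per edge, with the ratio-test fields;
#'   edges whose genes are absent from the GEM get `ok = FALSE`.
#' @export
ratio_test_edges <- function(gem, grn, annot, cond_a, cond_b,
                             alpha = 0.001, eps = 0.01) {
  rows <- lapply(seq_len(nrow(grn)), function(i) {
    tf <- grn$tf[i]; tr <- grn$target[i]
    if (!all(c(tf, tr) %in% gene_ids(gem)))
      return(data.frame(tf = tf, tr = tr, t_stat = NA_real_, p = NA_real_,
                        significant = FALSE, ok = FALSE))
    r <- tf_tr_ratio_test(gem, tf, tr, annot, cond_a, cond_b, alpha, eps)
    data.frame(tf = tf, tr = tr, t_stat = r$t_stat, p = r$p,
               significant = r$significant, ok = r$ok)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Categorize regulatory edges by DE status and ratio shift
#'
#' An edge is doubly significant when TF and target are both DEGs and the
#' TF/TR ratio test is significant; doubly-significant edges are
#' partitioned into the four directional categories by the two genes'
#' DE directions.
#'
#' @param grn data frame `tf`, `target`.
#' @param de data frame from [de_test].
#' @param ratio data frame from [ratio_test_edges] (keyed by `tf`, `tr`).
#' @return list with `assessments` (one row per edge: DE flags/directions,
#'   ratio significance, `doubly_significant`, `category`, `assessable`)
#'   and `counts` (`total`, `both_deg`, `ratio_significant`,
#'   `doubly_significant`, and the four categories).
#' @export
assess_regulatory_edges <- function(grn, de, ratio) {
  de_ix <- match(grn$tf, de$gene)
  tr_ix <- match(grn$target, de$gene)
  rt_ix <- match(paste(grn$tf, grn$target), paste(ratio$tf, ratio$tr))
  assessable <- !is.na(de_ix) & !is.na(tr_ix) & !is.na(rt_ix)
  tf_deg <- ifelse(assessable, de$is_deg[de_ix], NA)
  tr_deg <- ifelse(assessable, de$is_deg[tr_ix], NA)
  tf_dir <- ifelse(assessable, de$direction[de_ix], NA)
  tr_dir <- ifelse(assessable, de$direction[tr_ix], NA)
  rsig <- ifelse(assessable, ratio$significant[rt_ix], NA)
  both_deg <- !is.na(tf_deg) & !is.na(tr_deg) & tf_deg & tr_deg
  doubly <- both_deg & !is.na(rsig) & rsig
  category <- rep("none", nrow(grn))
  category[doubly & tf_dir == "up" & tr_dir == "up"] <- "TF & TR Up"
  category[doubly & tf_dir == "down" & tr_dir == "down"] <- "TF & TR Down"
  category[doubly & tf_dir == "up" & tr_dir == "down"] <- "TF Up & TR Down"
  category[doubly & tf_dir == "down" & tr_dir == "up"] <- "TF Down & TR Up"
  assessments <- data.frame(
    tf = grn$tf, tr = grn$target, assessable = assessable,
    tf_is_deg = tf_deg, tr_is_deg = tr_deg,
    tf_direction = tf_dir, tr_direction = tr_dir,
    ratio_significant = rsig, doubly_significant = doubly,
    category = category, stringsAsFactors = FALSE)
  counts <- category_counts(assessments)
  list(assessments = assessments, counts = counts)
}

#' Category counts for a regulatory-edge assessment table
#'
#' @param assessments the `assessments` element of
#'   [assess_regulatory_edges] (or a data frame with the same columns).
#' @return one-row data frame of the summary counts; the four directional
#'   categories always sum to `doubly_significant`.
#' @export
category_counts <- function(assessments) {
  data.frame(
    total = nrow(assessments),
    both_deg = sum(assessments$tf_is_deg & assessments$tr_is_deg, na.rm = TRUE),
    ratio_significant = sum(assessments$ratio_significant, na.rm = TRUE),
    doubly_significant = sum(assessments$doubly_significant, na.rm = TRUE),
    tf_tr_up = sum(assessments$category == "TF & TR Up"),
    tf_tr_down = sum(assessments$category == "TF & TR Down"),
    tf_up_tr_down = sum(assessments$category == "TF Up & TR Down"),
    tf_down_tr_up = sum(assessments$category == "TF Down & TR Up"))
}
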