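# Reliability screening over long-format feature tables.
#
# The interchange schema is a data.frame with columns
#   roi_id, condition, replicate, feature_name, value
# (one row per measurement). `roi_id` plays the subject role, `replicate`
# (scan/rescan) or `condition` the rater role depending on the analysis.

check_feature_table <- function(tbl, cols) {
  missing <- setdiff(cols, names(tbl))
  if (length(missing))
    stop("feature table is missing columns: ", paste(missing, collapse = ", "))
  # every grouping cell must carry the same feature set
  group_cols <- setdiff(cols, c("feature_name", "value"))
  grp <- interaction(tbl[group_cols], drop = TRUE)
  nm <- tapply(tbl$feature_name, grp,
               function(x) paste(sort(unique(x)), collapse = "\r"))
  if (length(unique(nm)) > 1L)
    stop("mismatched feature name sets across groups (",
         paste(group_cols, collapse = ", "), ")")
  invisible(TRUE)
}

# ICC(A,1|k) per feature from a subjects x raters layout
icc_by_feature <- function(tbl, subject_col, rater_col, form) {
  tbl <- tbl[order(tbl$feature_name, tbl[[subject_col]], tbl[[rater_col]]), ]
  subj <- sort(unique(tbl[[subject_col]]))
  raters <- sort(unique(tbl[[rater_col]]))
  n <- length(subj); k <- length(raters)
  if (n < 2L) stop("reliability screening needs >= 2 subjects")
  if (k < 2L) stop("reliability screening needs >= 2 raters")
  vals <- split(tbl$value, tbl$feature_name)
  recs <- lapply(names(vals), function(fn) {
    v <- vals[[fn]]
    if (length(v) != n * k)
      stop("feature ", fn, ": expected ", n * k, " cells, got ", length(v))
    mat <- matrix(v, nrow = n, ncol = k, byrow = TRUE)
    if (!all(is.finite(mat))) {
      return(data.frame(feature_name = fn, icc = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        label = "not_reliable", degenerate = TRUE))
    }
    res <- icc_absolute(mat, form = form)
    data.frame(feature_name = fn, icc = res$icc, ci_low = res$ci_low,
               ci_high = res$ci_high,
               label = if (res$degenerate) "not_reliable"
                       else classify_reliability(res),
               degenerate = res$degenerate)
  })
  do.call(rbind, recs)
}

#' Scan-rescan repeatability screening
#'
#' For every feature and condition, computes the single-measures
#' absolute-agreement ICC across scan/rescan replicates, with ROIs as
#' subjects, classifies it by the study's reliability index, and summarises
#' robust sets and their intersections across conditions. Features that are
#' constant over all cells (degenerate) are flagged and excluded from the
#' reliable/robust sets.
#'
#' @param tbl long-format data.frame with columns `roi_id`, `condition`,
#'   `replicate`, `feature_name`, `value`.
#' @return A `reliability_report`: list with `records` (per feature x
#'   condition data.frame), `robust_sets`, `reliable_sets` (named lists of
#'   feature names), `intersections` (data.frame `condition_set`,
#'   `robust_count`) and `form`.
#' @export
screen_features <- function(tbl) {
  check_feature_table(tbl, c("roi_id", "condition", "replicate",
                             "feature_name", "value"))
  conditions <- unique(tbl$condition)
  records <- do.call(rbind, lapply(conditions, function(cond) {
    sub <- tbl[tbl$condition == cond, ]
    rec <- icc_by_feature(sub, "roi_id", "replicate", form = "single")
    cbind(condition = cond, rec)
  }))
  build_reliability_report(records, form = "single")
}

#' Reproducibility screening across conditions
#'
#' Averages scan and rescan per (ROI, condition), then computes the
#' average-measures absolute-agreement ICC per feature with ROIs as subjects
#' and conditions as raters.
#'
#' @param tbl long-format table as in [screen_features()]; the `replicate`
#'   column is averaged out if present.
#' @return A `reliability_report` with one record per feature (condition
#'   column set to `"all"`).
#' @export
reproducibility_screen <- function(tbl) {
  check_feature_table(tbl, c("roi_id", "condition", "feature_name", "value"))
  if (length(unique(tbl$condition)) < 2L)
    stop("reproducibility_screen: need >= 2 conditions")
  agg <- stats::aggregate(value ~ roi_id + condition + feature_name,
                          data = tbl, FUN = mean)
  rec <- icc_by_feature(agg, "roi_id", "condition", form = "average")
  build_reliability_report(cbind(condition = "all", rec), form = "average")
}

build_reliability_report <- function(records, form) {
  rownames(records) <- NULL
  conds <- unique(records$condition)
  robust_sets <- lapply(conds, function(cc)
    records$feature_name[records$condition == cc &
                           records$label == "robust" & !records$degenerate])
  reliable_sets <- lapply(conds, function(cc)
    records$feature_name[records$condition == cc & !records$degenerate &
                           records$label %in% c("reliable", "robust")])
  names(robust_sets) <- names(reliable_sets) <- as.character(conds)
  structure(list(records = records, robust_sets = robust_sets,
                 reliable_sets = reliable_sets,
                 intersections = robust_intersections(robust_sets),
                 form = form),
            class = "reliability_report")
}

#' Sizes of robust-set intersections across conditions
#'
#' @param robust_sets named list of character vectors of feature names.
#' @return data.frame with `condition_set` (conditions joined by `+`) and
#'   `robust_count`: each single condition, each pair, and the intersection
#'   of all conditions.
#' @export
robust_intersections <- function(robust_sets) {
  conds <- names(robust_sets)
  rows <- lapply(conds, function(cc)
    data.frame(condition_set = cc,
               robust_count = length(robust_sets[[cc]])))
  if (length(conds) > 1L) {
    if (length(conds) > 2L) {
      prs <- utils::combn(conds, 2, simplify = FALSE)
      rows <- c(rows, lapply(prs, function(p)
        data.frame(condition_set = paste(p, collapse = "+"),
                   robust_count = length(Reduce(intersect,
                                                robust_sets[p])))))
    }
    rows <- c(rows, list(data.frame(
      condition_set = paste(conds, collapse = "+"),
      robust_count = length(Reduce(intersect, robust_sets)))))
  }
  do.call(rbind, rows)
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("reliability_report (%s-measures ICC): %d features x %d condition(s)\n",
              x$form, length(unique(x$records$feature_name)),
              length(unique(x$records$condition))))
  for (cc in names(x$robust_sets)) {
    cat(sprintf("  %s: %d robust, %d reliable, %d degenerate\n", cc,
                length(x$robust_sets[[cc]]),
                length(x$reliable_sets[[cc]]),
                sum(x$records$degenerate[x$records$condition == cc])))
  }
  invisible(x)
}

#' Flag features correlated with segmentation volume
#'
#' Pearson correlation of each feature against segmentation volume over a
#' series of segmentation sizes; a feature is flagged when r > 0.8 (signed,
#' strict, the study's rule) or |r| > 0.8 with `absolute = TRUE`. Constant
#' features have undefined r and are recorded as degenerate, never flagged.
#'
#' @param tbl data.frame with columns `feature_name`, `volume`, `value`
#'   (one row per feature per segmentation volume; values typically
#'   volume-condition means). `volume` may be the nominal mm^3 or the
#'   measured `original_shape_MeshVolume`.
#' @param threshold flag threshold on r (default 0.8).
#' @param absolute use |r| instead of signed r.
#' @return data.frame `feature_name`, `r`, `flagged`, `degenerate`.
#' @export
volume_correlation <- function(tbl, threshold = 0.8, absolute = FALSE) {
  check_feature_table(tbl, c("feature_name", "volume", "value"))
  if (length(unique(tbl$volume)) < 3L)
    stop("volume_correlation: need >= 3 volumes")
  tbl <- tbl[order(tbl$feature_name, tbl$volume), ]
  vals <- split(tbl$value, tbl$feature_name)
  vols <- split(tbl$volume, tbl$feature_name)
  out <- lapply(names(vals), function(fn) {
    v <- vals[[fn]]; x <- vols[[fn]]
    if (!all(is.finite(v)) || stats::sd(v) == 0) {
      return(data.frame(feature_name = fn, r = NA_real_, flagged = FALSE,
                        degenerate = TRUE))
    }
    r <- stats::cor(x, v)
    stat <- if (absolute) abs(r) else r
    data.frame(feature_name = fn, r = r, flagged = stat > threshold,
               degenerate = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Two-arm cohort differentiation on robust features
#'
#' Paired two-tailed t-test per feature across index-paired subjects of the
#' two arms, restricted to a supplied robust feature set; significance at
#' p < 0.05 (raw p-values by default, Benjamini-Hochberg optional).
#'
#' @param tbl data.frame with columns `cohort` (two levels), `subject`
#'   (pairing index 1..n within each arm), `feature_name`, `value`.
#' @param robust_set character vector of feature names to test; `NULL`
#'   tests every feature.
#' @param alpha significance level (default 0.05).
#' @param p_adjust multiplicity correction passed to [stats::p.adjust()]
#'   (default `"none"`, the study's convention).
#' @return data.frame `feature_name`, `mean_diff`, `t`, `p`, `significant`.
#' @export
compare_cohorts <- function(tbl, robust_set = NULL, alpha = 0.05,
                            p_adjust = "none") {
  check_feature_table(tbl, c("cohort", "subject", "feature_name", "value"))
  arms <- sort(unique(tbl$cohort))
  if (length(arms) != 2L) stop("compare_cohorts: need exactly 2 cohorts")
  a <- tbl[tbl$cohort == arms[1], ]
  b <- tbl[tbl$cohort == arms[2], ]
  if (length(unique(a$subject)) != length(unique(b$subject)))
    stop("compare_cohorts: unequal arm sizes; index pairing impossible")
  if (!is.null(robust_set)) {
    a <- a[a$feature_name %in% robust_set, ]
    b <- b[b$feature_name %in% robust_set, ]
    if (nrow(a) == 0L)
      return(data.frame(feature_name = character(), mean_diff = numeric(),
                        t = numeric(), p = numeric(),
                        significant = logical()))
  }
  a <- a[order(a$feature_name, a$subject), ]
  b <- b[order(b$feature_name, b$subject), ]
  va <- split(a$value, a$feature_name)
  vb <- split(b$value, b$feature_name)
  out <- lapply(names(va), function(fn) {
    x <- va[[fn]]; y <- vb[[fn]]
    d <- x - y
    if (stats::sd(d) == 0) {
      # degenerate paired test: identical pairs give t = 0, p = 1
      tt <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      pp <- if (mean(d) == 0) 1 else 0
    } else {
      ht <- stats::t.test(x, y, paired = TRUE)
      tt <- unname(ht$statistic)
      pp <- ht$p.value
    }
    data.frame(feature_name = fn, mean_diff = mean(d), t = tt, p = pp)
  })
  res <- do.call(rbind, out)
  res$p_adjusted <- stats::p.adjust(res$p, method = p_adjust)
  res$significant <- res$p_adjusted < alpha
  rownames(res) <- NULL
  res
}

#' Turn a list of per-ROI feature vectors into the long screening format
#'
#' @param vectors list of named numeric feature vectors.
#' @param roi_id,condition,replicate vectors (recycled) labelling each
#'   element of `vectors`.
#' @return Long-format data.frame with the screening schema.
#' @export
feature_long <- function(vectors, roi_id, condition = "default",
                         replicate = 1L) {
  roi_id <- rep_len(roi_id, length(vectors))
  condition <- rep_len(condition, length(vectors))
  replicate <- rep_len(replicate, length(vectors))
  do.call(rbind, lapply(seq_along(vectors), function(i) {
    fv <- vectors[[i]]
    data.frame(roi_id = roi_id[i], condition = condition[i],
               replicate = replicate[i], feature_name = names(fv),
               value = unname(fv))
  }))
}
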