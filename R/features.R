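INDEX_NAMES <- c("KI", "HI", "BDI", "SEI", "PEI")

# Evaluate one index on one IMF, mapping undefined-index conditions to NA
# (kept in the table, never dropped silently).
eval_index <- function(name, imf, params) {
  tryCatch(switch(name,
                  KI  = katz_fd(imf),
                  HI  = higuchi_fd(imf, params),
                  BDI = box_dimension(imf, params),
                  SEI = shannon_entropy(imf, params),
                  PEI = permutation_entropy(imf, params)),
           scdemd_error = function(e) NA_real_)
}

#' Extract the 30-feature vector of a one-minute window
#'
#' Decomposes the window into its first `max_imfs` intrinsic mode functions
#' and evaluates the five nonlinear indices on each, yielding
#' `5 x max_imfs` features (30 with the default six modes). Indices that
#' are undefined on a degenerate mode are recorded as `NA`.
#'
#' @param window An `ecg_window` (or plain numeric vector).
#' @param emd_cfg An [emd_config()].
#' @param idx_params An [index_params()].
#' @return A data.frame with columns `subject_id`, `label`, `minute`,
#'   `index`, `imf`, `value` (one row per feature).
#' @export
extract_features <- function(window, emd_cfg = emd_config(),
                             idx_params = index_params()) {
  if (is.numeric(window))
    window <- ecg_window(window, 128, 0L, "anon", "normal")
  dec <- emd_decompose(window, emd_cfg)
  n_imf <- emd_cfg$max_imfs
  grid <- expand.grid(index = INDEX_NAMES, imf = seq_len(n_imf),
                      stringsAsFactors = FALSE)
  vals <- mapply(function(ix, k) {
    if (k > length(dec$imfs)) return(NA_real_)
    eval_index(ix, dec$imfs[[k]], idx_params)
  }, grid$index, grid$imf)
  data.frame(subject_id = window$subject_id, label = window$label,
             minute = window$minute_index, index = grid$index,
             imf = grid$imf, value = as.numeric(vals),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build the cohort feature table
#'
#' SCD records contribute one feature vector per pre-onset minute
#' (`n_minutes` windows each); normal records contribute a single feature
#' vector from a seeded random one-minute window.
#'
#' @param records List of [ecg_record()]s (both labels present).
#' @param n_minutes Pre-onset minutes per SCD record (default 25).
#' @param seed Seed for the normal-group window draws.
#' @param emd_cfg,idx_params Pipeline configuration objects.
#' @param progress Print per-record progress to stderr.
#' @return A tidy data.frame (one row per feature per window).
#' @export
build_feature_table <- function(records, n_minutes = 25L, seed = 1L,
                                emd_cfg = emd_config(),
                                idx_params = index_params(),
                                progress = FALSE) {
  labels <- vapply(records, function(r) r$label, character(1))
  if (!any(labels == "normal") || !any(labels == "scd"))
    abort("cohort must contain both normal and scd records",
          "scdemd_config_error")
  out <- list()
  for (i in seq_along(records)) {
    rec <- records[[i]]
    if (progress)
      message(sprintf("[%d/%d] %s (%s)", i, length(records),
                      rec$subject_id, rec$label))
    wins <- if (rec$label == "scd") {
      segment_pre_onset(rec, n_minutes)
    } else {
      list(random_normal_window(rec, derive_seed(seed, i)))
    }
    out[[i]] <- do.call(rbind, lapply(wins, extract_features,
                                      emd_cfg = emd_cfg,
                                      idx_params = idx_params))
  }
  do.call(rbind, out)
}

#' One-way ANOVA for two groups
#'
#' Classical equal-variance one-way analysis of variance, with the p-value
#' taken from the F(1, n1+n2-2) distribution. With two groups F equals the
#' square of the pooled-variance two-sample t statistic.
#'
#' @param group_a,group_b Numeric vectors (each length >= 2, finite).
#' @return A list with elements `F` and `p_value`.
#' @export
#' @examples
#' one_way_anova(c(1, 2, 3), c(2, 3, 4))  # F = 1.5
one_way_anova <- function(group_a, group_b) {
  a <- group_a[is.finite(group_a)]
  b <- group_b[is.finite(group_b)]
  if (length(a) < 2L || length(b) < 2L)
    abort("each group needs >= 2 finite values", "scdemd_config_error")
  ssw <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
  gm <- mean(c(a, b))
  ssb <- length(a) * (mean(a) - gm)^2 + length(b) * (mean(b) - gm)^2
  if (ssw == 0 && ssb == 0)
    abort("all values identical: ANOVA undefined", "scdemd_undefined_index")
  if (ssw == 0) return(list(F = Inf, p_value = 0))
  ht <- stats::oneway.test(
    value ~ grp,
    data = data.frame(value = c(a, b),
                      grp = rep(c("a", "b"), c(length(a), length(b)))),
    var.equal = TRUE)
  list(F = unname(ht$statistic), p_value = unname(ht$p.value))
}

#' Rank features by between-group significance
#'
#' Runs [one_way_anova()] of normal vs SCD values for each of the 30
#' `(index, imf)` features and ranks them by ascending p-value. With
#' `scope = "pooled"` (default) all SCD minutes are pooled against the
#' normal group, matching how the final feature pair is chosen; with
#' `scope = "per_minute"` a separate report is produced for every pre-onset
#' minute. Features with too few defined values are excluded from the
#' ranking with a warning.
#'
#' @param table Feature table from [build_feature_table()].
#' @param k Number of top features to select (default 2).
#' @param scope `"pooled"` or `"per_minute"`.
#' @param fdr Apply Benjamini-Hochberg adjustment to the reported p-values
#'   (ranking then uses adjusted values; default off, matching the raw-p
#'   screening).
#' @return A list with `report` (data.frame: minute [per-minute scope only],
#'   index, imf, F, p, group means/sds) and `top` (data.frame of the `k`
#'   selected features from the pooled ranking).
#' @export
select_features <- function(table, k = 2L, scope = c("pooled", "per_minute"),
                            fdr = FALSE) {
  scope <- match.arg(scope)
  if (!all(c("normal", "scd") %in% table$label))
    abort("feature table must contain both labels", "scdemd_config_error")
  anova_block <- function(tab, minute = NA_integer_) {
    feats <- unique(tab[, c("index", "imf")])
    rows <- lapply(seq_len(nrow(feats)), function(i) {
      sel <- tab$index == feats$index[i] & tab$imf == feats$imf[i]
      a <- tab$value[sel & tab$label == "normal"]
      b <- tab$value[sel & tab$label == "scd"]
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      if (length(a) < 2L || length(b) < 2L) {
        warning(sprintf("feature (%s, IMF%d) excluded: too few defined values",
                        feats$index[i], feats$imf[i]))
        return(NULL)
      }
      an <- tryCatch(one_way_anova(a, b), scdemd_error = function(e) NULL)
      if (is.null(an)) return(NULL)
      data.frame(minute = minute, index = feats$index[i], imf = feats$imf[i],
                 F = an$F, p = an$p_value,
                 mean_normal = mean(a), mean_scd = mean(b),
                 sd_normal = stats::sd(a), sd_scd = stats::sd(b))
    })
    blk <- do.call(rbind, rows)
    if (!is.null(blk) && fdr) blk$p <- stats::p.adjust(blk$p, "BH")
    blk
  }
  pooled <- anova_block(table)
  pooled <- pooled[order(pooled$p, -pooled$F), ]
  rownames(pooled) <- NULL
  report <- if (scope == "per_minute") {
    minutes <- sort(unique(table$minute[table$label == "scd"]))
    do.call(rbind, lapply(minutes, function(m) {
      blk <- anova_block(table[table$label == "normal" |
                                 table$minute == m, ], m)
      blk[order(blk$p), ]
    }))
  } else {
    pooled
  }
  rownames(report) <- NULL
  list(report = report, top = utils::head(pooled, k), scope = scope)
}

#' Pivot selected features into a classifier design matrix
#'
#' @param table Tidy feature table.
#' @param features data.frame with columns `index` and `imf` naming the
#'   selected features (e.g. the `top` element of [select_features()]).
#' @return A data.frame with one row per window: `subject_id`, `label`,
#'   `minute`, then one numeric column per selected feature (named
#'   `"<index>.imf<k>"`). Rows with any undefined selected feature are
#'   dropped.
#' @export
feature_matrix <- function(table, features) {
  cols <- lapply(seq_len(nrow(features)), function(i) {
    sel <- table$index == features$index[i] & table$imf == features$imf[i]
    sub <- table[sel, c("subject_id", "label", "minute", "value")]
    names(sub)[4L] <- sprintf("%s.imf%d", features$index[i], features$imf[i])
    sub
  })
  out <- Reduce(function(a, b) merge(a, b, by = c("subject_id", "label", "minute")),
                cols)
  out <- out[stats::complete.cases(out), ]
  out[order(out$subject_id, out$minute), , drop = FALSE]
}
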