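#' Specification of the behaviour-seascape additive model
#'
#' A binomial (logit link) generalised additive mixed model of the most
#' probable discrete behavioural state (ARS = 1, transit = 0) on smooth
#' functions of seascape covariates, with a per-whale random intercept
#' (`s(tag_id, bs = "re")`). Smooth significance is the Wald-type chi-square
#' test on the spline coefficients.
#'
#' @param smooths character vector of covariate names to receive smooths.
#' @param k basis dimension per smooth (default 10).
#' @param random name of the grouping factor for the random intercept
#'   (default `"tag_id"`).
#' @param linear if TRUE all terms enter linearly (no smoothing) — mostly a
#'   testing device: the model then reduces to penalised-free logistic
#'   regression.
#' @return object of class `gamm_spec`.
#' @export
gamm_spec <- function(smooths, k = 10, random = "tag_id", linear = FALSE) {
  stopifnot(is.character(smooths), length(smooths) >= 1, k >= 3)
  structure(list(smooths = smooths, k = k, random = random, linear = linear),
            class = "gamm_spec")
}

#' Fit the binomial behaviour-seascape GAMM
#'
#' @param matrix covariate data.frame (e.g. from [extract_covariates()]) with
#'   a `mode_state` column in {1, 2} (or an `ars` 0/1 column) and a `tag_id`
#'   column. Rows with missing covariates are dropped listwise (counted).
#' @param spec a [gamm_spec()].
#' @param min_rows minimum usable rows (default 30).
#' @return object of class `ars_gamm`: the mgcv fit plus an extracted
#'   `smooth_table` (chi-square, edf, p per covariate), `intercept` row,
#'   `r_sq` (adjusted) and `n`.
#' @export
fit_gamm <- function(matrix, spec, min_rows = 30) {
  stopifnot(inherits(spec, "gamm_spec"))
  df <- as.data.frame(matrix)
  if (!"ars" %in% names(df)) {
    stopifnot("mode_state" %in% names(df))
    stopifnot(all(df$mode_state %in% c(1, 2, NA)))
    df$ars <- as.integer(df$mode_state == 2)
  }
  need <- c("ars", spec$smooths, spec$random)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  keep <- stats::complete.cases(df[, need, drop = FALSE])
  n_dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  if (nrow(df) < min_rows) stop("too few usable rows (", nrow(df), ")")
  if (length(unique(df$ars)) < 2)
    stop("degenerate response: all locations in one behavioural state")
  df[[spec$random]] <- factor(df[[spec$random]])
  use_re <- nlevels(df[[spec$random]]) >= 2
  ## guard against rank deficiency from constant covariates
  const <- spec$smooths[vapply(df[spec$smooths], function(v) stats::sd(v) == 0, TRUE)]
  if (length(const))
    stop("constant covariate column(s): ", paste(const, collapse = ", "))

  terms <- if (spec$linear) spec$smooths
           else sprintf("s(%s, k = %d)", spec$smooths, spec$k)
  if (use_re) terms <- c(terms, sprintf("s(%s, bs = \"re\")", spec$random))
  fml <- stats::as.formula(paste("ars ~", paste(terms, collapse = " + ")))
  fit <- mgcv::gam(fml, family = stats::binomial(link = "logit"),
                   data = df, method = "REML")
  sm <- summary(fit)
  st <- sm$s.table
  if (!is.null(st)) {
    keep_rows <- !grepl(paste0("^s\\(", spec$random, "\\)"), rownames(st))
    st <- st[keep_rows, , drop = FALSE]
    smooth_table <- data.frame(variable = gsub("^s\\(|\\)$", "", rownames(st)),
                               edf = st[, "edf"],
                               chi_sq = st[, "Chi.sq"],
                               p_value = st[, "p-value"],
                               row.names = NULL)
  } else smooth_table <- NULL
  pt <- sm$p.table
  intercept <- data.frame(estimate = pt["(Intercept)", 1],
                          se = pt["(Intercept)", 2],
                          z = pt["(Intercept)", 3],
                          p_value = pt["(Intercept)", 4])
  if (spec$linear) {
    lin <- pt[setdiff(rownames(pt), "(Intercept)"), , drop = FALSE]
    smooth_table <- data.frame(variable = rownames(lin),
                               edf = 1,
                               chi_sq = lin[, 3]^2,
                               p_value = lin[, 4], row.names = NULL)
  }
  structure(list(fit = fit, spec = spec, smooth_table = smooth_table,
                 intercept = intercept, r_sq = sm$r.sq,
                 n = nrow(df), n_dropped = n_dropped),
            class = "ars_gamm")
}

#' @export
print.ars_gamm <- function(x, ...) {
  cat(sprintf("Binomial ARS ~ seascape GAMM (n = %d, adj. R^2 = %.3f)\n",
              x$n, x$r_sq))
  cat(sprintf("intercept %.4f +/- %.4f (z = %.2f)\n",
              x$intercept$estimate, x$intercept$se, x$intercept$z))
  print(transform(x$smooth_table, edf = round(edf, 2), chi_sq = round(chi_sq, 3),
                  p_value = signif(p_value, 3)))
  invisible(x)
}

#' Smooth effect curves
#'
#' Pointwise smooth effects on the linear predictor scale, mirroring the
#' usual partial-effect panels.
#'
#' @param x an `ars_gamm`.
#' @param variable covariate name.
#' @param n grid points.
#' @return data.frame `x, effect, se`.
#' @export
smooth_curve <- function(x, variable, n = 100) {
  stopifnot(inherits(x, "ars_gamm"), variable %in% x$spec$smooths)
  dat <- x$fit$model
  grid <- dat[rep(1, n), , drop = FALSE]
  for (v in x$spec$smooths) grid[[v]] <- stats::median(dat[[v]])
  grid[[variable]] <- seq(min(dat[[variable]]), max(dat[[variable]]),
                          length.out = n)
  pr <- mgcv::predict.gam(x$fit, newdata = grid, type = "terms",
                          se.fit = TRUE,
                          exclude = sprintf("s(%s)", x$spec$random))
  cn <- grep(paste0("\\(", variable, "[,)]"), colnames(pr$fit), value = TRUE)
  if (!length(cn)) cn <- variable
  data.frame(x = grid[[variable]], effect = pr$fit[, cn[1]],
             se = pr$se.fit[, cn[1]])
}

#' Multiple-imputation significance of seascape covariates
#'
#' Propagates location and behavioural-state uncertainty into the habitat
#' model: each iteration takes one joint posterior draw of locations and
#' states from the state-space fit (alternating between the two retained
#' chains), freshly extracts the seascape covariates at the drawn locations,
#' refits the GAMM, and records which covariates achieve p < 0.05. The
#' summary is, per covariate, the count of significant iterations out of
#' `n_iter`. A failed refit is logged and counted as non-significant for
#' every covariate; the loop never aborts.
#'
#' @param fit an `hssm` fit providing posterior draws.
#' @param fields a [seascape_fields()] object covering the drawn locations.
#' @param spec a [gamm_spec()].
#' @param n_iter number of refits (default 100).
#' @param mask optional [region_mask()] restricting rows per iteration.
#' @param extract_args list of extra arguments to [extract_covariates()].
#' @param seed integer seed for draw selection.
#' @return object of class `imputation_summary`: data.frame `counts`
#'   (`variable, n_significant, n_iter`), matrix `chi_sq` of statistics
#'   across refits, `n_failed`.
#' @export
imputation_significance <- function(fit, fields, spec, n_iter = 100,
                                    mask = NULL, extract_args = list(),
                                    seed = 1L) {
  stopifnot(inherits(fit, "hssm"), inherits(spec, "gamm_spec"))
  set.seed(as.integer(seed))
  chains <- sort(unique(fit$draws$chain))
  idx_by_chain <- lapply(chains, function(ch) which(fit$draws$chain == ch))
  vars <- spec$smooths
  counts <- setNames(integer(length(vars)), vars)
  chi <- matrix(NA_real_, n_iter, length(vars), dimnames = list(NULL, vars))
  n_failed <- 0L
  for (m in seq_len(n_iter)) {
    ## alternate chains; sample a retained draw within the chain
    ch <- chains[((m - 1) %% length(chains)) + 1]
    pool <- idx_by_chain[[match(ch, chains)]]
    ix <- pool[sample.int(length(pool), 1)]
    dr <- posterior_draws(fit, ix)
    if (!is.null(mask)) dr <- dr[mask(dr$lon, dr$lat), , drop = FALSE]
    res <- try({
      cm <- do.call(extract_covariates,
                    c(list(series = dr, fields = fields, vars = vars),
                      extract_args))
      cm$ars <- as.integer(dr$b == 2)  # rows of cm mirror rows of dr
      g <- fit_gamm(cm, spec)
      pv <- setNames(g$smooth_table$p_value, g$smooth_table$variable)
      cs <- setNames(g$smooth_table$chi_sq, g$smooth_table$variable)
      sig <- names(pv)[pv < 0.05]
      counts[sig] <- counts[sig] + 1L
      chi[m, names(cs)] <- cs
      TRUE
    }, silent = TRUE)
    if (inherits(res, "try-error")) n_failed <- n_failed + 1L
  }
  structure(list(counts = data.frame(variable = vars,
                                     n_significant = unname(counts[vars]),
                                     n_iter = n_iter),
                 chi_sq = chi, n_failed = n_failed),
            class = "imputation_summary")
}

#' @export
print.imputation_summary <- function(x, ...) {
  cat("Multiple-imputation significance (", x$counts$n_iter[1], " refits, ",
      x$n_failed, " failed)\n", sep = "")
  print(x$counts)
  invisible(x)
}
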