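#' Summarise a compiled condition
#'
#' Per structure and day: mean, standard error of the mean and replicate
#' count under the compile-stage accounting (occluded replicates excluded,
#' absent late roots counted as zeros). The root-6 inclusion rule is applied
#' here too so summaries never report a structure hidden from plots.
#'
#' @param compiled a `compiled_condition`.
#' @param include_root6 `NULL` (default) to decide via [root6_included()],
#'   or an explicit logical.
#' @param root6_threshold passed to [root6_included()].
#' @return data.frame with columns `genotype`, `condition`, `structure`,
#'   `day`, `mean_mm`, `sem_mm` (`NA` unless `n >= 2`) and `n`.
#' @export
summarize_condition <- function(compiled, include_root6 = NULL,
                                root6_threshold = 3L) {
  stopifnot(inherits(compiled, "compiled_condition"))
  structures <- analysis_structures(compiled, compiled, include_root6,
                                    root6_threshold)
  res <- list()
  for (s in structures) {
    for (d in 0:2) {
      rows <- compiled[compiled$structure == s & compiled$day == d, ]
      use <- rows$status != "occluded"
      n <- sum(use)
      vals <- rows$length_mm[use]
      res[[length(res) + 1L]] <- data.frame(
        genotype = compiled$genotype[1L], condition = compiled$condition[1L],
        structure = s, day = d,
        mean_mm = if (n > 0L) mean(vals) else NA_real_,
        sem_mm = if (n >= 2L) stats::sd(vals) / sqrt(n) else NA_real_,
        n = n, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# structures entering summaries/stats, honouring the root-6 rule across both
# conditions (evidence in either condition triggers inclusion)
analysis_structures <- function(ww, ws, include_root6, threshold) {
  base <- c("shoot", paste0("root", 1:5))
  r6 <- if (is.null(include_root6)) {
    root6_included(ww, threshold) || root6_included(ws, threshold)
  } else {
    isTRUE(include_root6)
  }
  has_rows <- "root6" %in% c(attr(ww, "structures"), attr(ws, "structures"))
  c(base, if (r6 && has_rows) "root6")
}

#' Fit the per-structure mixed model
#'
#' Fits `length_mm ~ condition * day` (day categorical) with random
#' intercepts for plate and for seedling within plate, by REML via
#' \pkg{lmerTest}. Occluded rows are dropped; absent late roots enter as
#' true zeros (they count toward replicate numbers). Repeated measures on
#' the same seedling motivate the seedling term; plates are the blocks the
#' treatment is applied to.
#'
#' Variance components estimated at zero make the fit singular; the fallback
#' ladder is deterministic: drop the seedling intercept, then also the plate
#' intercept (a fixed-effects-only least-squares fit, issued with a
#' warning). The fallback used is recorded on the returned object.
#'
#' @param ww,ws `compiled_condition`s for the well-watered and
#'   water-stressed treatments.
#' @param structure structure to fit (e.g. `"root1"`).
#' @return an object of class `structure_fit`: list with elements `model`
#'   (an `lmerModLmerTest` or `lm`), `structure`, `fallback` (one of
#'   `"none"`, `"dropped_seedling"`, `"dropped_plate"`, `"fixed_only"`),
#'   `n_obs` and `data`.
#' @export
fit_structure_model <- function(ww, ws, structure) {
  stopifnot(inherits(ww, "compiled_condition"),
            inherits(ws, "compiled_condition"))
  if (ww$condition[1L] != "WW" || ws$condition[1L] != "WS") {
    stop("expected ww to be condition WW and ws to be condition WS",
         call. = FALSE)
  }
  df <- rbind(as.data.frame(ww), as.data.frame(ws))
  df <- df[df$structure == structure, ]
  if (nrow(df) == 0L) {
    stop("no rows for structure ", sQuote(structure), call. = FALSE)
  }
  df <- df[df$status != "occluded", ]
  if (nrow(df) == 0L) {
    stop("every replicate of structure ", sQuote(structure),
         " is occluded; nothing to fit", call. = FALSE)
  }
  df$condition <- factor(df$condition, levels = c("WW", "WS"))
  df$day <- factor(df$day, levels = 0:2)
  # plates are nested in condition, seedlings in plates
  df$plate_id <- factor(paste0(df$condition, df$plate))
  df$seedling_id <- factor(paste0(df$plate_id, ".s", df$seedling))

  fits <- list(
    none = length_mm ~ condition * day + (1 | plate_id) + (1 | seedling_id),
    dropped_seedling = length_mm ~ condition * day + (1 | plate_id)
  )
  model <- NULL
  fallback <- "fixed_only"
  for (nm in names(fits)) {
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lmerTest::lmer(fits[[nm]], data = df, REML = TRUE)
      )),
      error = function(e) NULL
    )
    if (!is.null(fit) && !lme4::isSingular(fit, tol = 1e-6)) {
      model <- fit
      fallback <- nm
      break
    }
  }
  if (is.null(model)) {
    # both random terms dropped: plain least squares on the fixed effects
    warning("random effects inestimable for ", sQuote(structure),
            "; degrading to a fixed-effects-only fit", call. = FALSE)
    model <- stats::lm(length_mm ~ condition * day, data = df)
  }
  out <- list(model = model, structure = structure, fallback = fallback,
              n_obs = nrow(df), data = df)
  class(out) <- "structure_fit"
  out
}

#' @export
print.structure_fit <- function(x, ...) {
  cat(sprintf("<structure_fit> %s: %d observations, fallback = %s\n",
              x$structure, x$n_obs, x$fallback))
  print(x$model)
  invisible(x)
}

#' Per-timepoint WS - WW contrasts for a fitted structure
#'
#' Estimated-marginal-means contrasts of condition within each day, with
#' Satterthwaite degrees of freedom for mixed fits. No multiplicity
#' correction is applied by default, matching the flat 0.05 cutoff used to
#' colour difference plots; set `adjust = "holm"` to correct across days.
#'
#' @param fit a `structure_fit`.
#' @param alpha significance cutoff (default 0.05).
#' @param adjust p-value adjustment across the three days (default
#'   `"none"`).
#' @return a data.frame with columns `structure`, `day`, `estimate_mm`
#'   (WS - WW), `se_mm`, `df`, `p_value` and `significant`.
#' @export
posthoc_differences <- function(fit, alpha = 0.05, adjust = "none") {
  stopifnot(inherits(fit, "structure_fit"), alpha > 0, alpha < 1)
  emm <- emmeans::emmeans(fit$model, ~ condition | day,
                          lmer.df = "satterthwaite", data = fit$data)
  ctr <- emmeans::contrast(emm, method = list("WS - WW" = c(-1, 1)),
                           adjust = adjust)
  s <- as.data.frame(summary(ctr))
  out <- data.frame(
    structure = fit$structure,
    day = as.integer(as.character(s$day)),
    estimate_mm = s$estimate,
    se_mm = s$SE,
    df = s$df,
    p_value = s$p.value,
    stringsAsFactors = FALSE
  )
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out <- out[order(out$day), ]
  rownames(out) <- NULL
  out
}

#' WS versus WW difference table over all analysed structures
#'
#' Fits every analysed structure (shoot and roots 1-5, plus root 6 when the
#' inclusion rule admits it) and stacks the per-day WS - WW contrasts into
#' one table, in stable anatomical order.
#'
#' @param ww,ws `compiled_condition`s for the two treatments.
#' @param alpha significance cutoff (default 0.05).
#' @param include_root6,root6_threshold root-6 rule controls, as in
#'   [summarize_condition()].
#' @param adjust p-value adjustment across days within a structure.
#' @return a data.frame of class `difference_table`: columns as in
#'   [posthoc_differences()]; attributes `alpha` and `fallbacks` (named
#'   character vector of the fallback used per structure).
#' @export
summary_ws_vs_ww <- function(ww, ws, alpha = 0.05, include_root6 = NULL,
                             root6_threshold = 3L, adjust = "none") {
  stopifnot(inherits(ww, "compiled_condition"),
            inherits(ws, "compiled_condition"))
  if (nrow(ww) == 0L || nrow(ws) == 0L) {
    stop("both conditions must contain data", call. = FALSE)
  }
  structures <- analysis_structures(ww, ws, include_root6, root6_threshold)
  pieces <- list()
  fallbacks <- character()
  for (s in structures) {
    fit <- fit_structure_model(ww, ws, s)
    fallbacks[s] <- fit$fallback
    pieces[[s]] <- posthoc_differences(fit, alpha = alpha, adjust = adjust)
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "fallbacks") <- fallbacks
  class(out) <- c("difference_table", "data.frame")
  out
}

#' @export
print.difference_table <- function(x, ...) {
  cat(sprintf("<difference_table> WS - WW, %d structures x 3 days, alpha = %g\n",
              length(unique(x$structure)), attr(x, "alpha")))
  print.data.frame(as.data.frame(x), digits = 4, ...)
  invisible(x)
}
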