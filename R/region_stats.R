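# Region-level statistics: one-way ANOVA across lamina propria regions,
# Tukey pairwise comparisons (Tukey-Kramer for unbalanced groups), and
# table-style per-region summaries.

as_grouped <- function(gf) {
  if (is.data.frame(gf)) {
    stopifnot(all(c("value", "region") %in% names(gf)))
    df <- data.frame(value = gf$value, region = factor(gf$region))
  } else if (is.list(gf)) {
    df <- data.frame(value = unlist(gf, use.names = FALSE),
                     region = factor(rep(names(gf), lengths(gf))))
  } else stop("expected a data.frame(value, region) or a named list")
  tab <- table(df$region)
  if (length(tab) < 2 || any(tab < 2))
    stop("need >= 2 groups with >= 2 values each")
  df
}

#' One-way ANOVA across regions
#'
#' Classic between/within mean-square F statistic and upper-tail p-value
#' for a feature grouped by region.
#'
#' @param gf a data.frame with columns `value` and `region`, or a named
#'   list mapping region to values. Every group needs >= 2 values.
#' @return A list: `F`, `p_value`, `df_between`, `df_within`, and the
#'   fitted `aov` object.
#' @export
anova_oneway <- function(gf) {
  df <- as_grouped(gf)
  if (stats::var(df$value) == 0)
    stop("all values identical; F is undefined")
  fit <- stats::aov(value ~ region, data = df)
  s <- summary(fit)[[1]]
  list(F = s$`F value`[1], p_value = s$`Pr(>F)`[1],
       df_between = s$Df[1], df_within = s$Df[2], fit = fit)
}

#' Tukey pairwise comparisons across regions
#'
#' Studentized-range (Tukey HSD) p-values for every pair of regions, with
#' the Tukey-Kramer adjustment for unequal group sizes. Each pair is
#' additionally flagged at three conventional significance tiers, including
#' the "extremely significant" P < 0.001 tier.
#'
#' @inheritParams anova_oneway
#' @return data.frame: `group1`, `group2`, `diff`, `p_value`, `sig_05`,
#'   `sig_01`, `sig_001`.
#' @export
tukey_pairwise <- function(gf) {
  df <- as_grouped(gf)
  fit <- stats::aov(value ~ region, data = df)
  tk <- stats::TukeyHSD(fit)$region
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  data.frame(group1 = vapply(pairs, `[`, "", 1),
             group2 = vapply(pairs, `[`, "", 2),
             diff = unname(tk[, "diff"]),
             p_value = unname(tk[, "p adj"]),
             sig_05 = unname(tk[, "p adj"]) < 0.05,
             sig_01 = unname(tk[, "p adj"]) < 0.01,
             sig_001 = unname(tk[, "p adj"]) < 0.001,
             row.names = NULL)
}

# Feature columns emitted per table layout; cells with no data stay empty.
TABLE_FEATURES <- list(
  shg_table = c("thickness_um", "fiber_od_um", "theta_deg", "anisotropy",
                "fenestration_frac"),
  oct_table = c("thickness_um", "mu_t_per_mm"))

#' Per-region summary table (SHG or OCT layout)
#'
#' Emits mean and SD per region for the feature set of the chosen layout:
#' the SHG table carries thickness, fiber outer diameter, orientation,
#' anisotropy and fenestration fraction; the OCT table carries thickness
#' and the relative attenuation coefficient. Features absent from the
#' input are emitted as empty (NA) columns, never fabricated.
#'
#' @param records data.frame with a `region` column plus any of the layout
#'   feature columns, one row per window/measurement.
#' @param layout `"shg_table"` or `"oct_table"`.
#' @return data.frame with one row per region (in anatomical order):
#'   `region`, `n`, and `<feature>_mean` / `<feature>_sd` per feature.
#' @export
summarize_tables <- function(records, layout = c("shg_table", "oct_table")) {
  layout <- match.arg(layout)
  feats <- TABLE_FEATURES[[layout]]
  order_ref <- if (layout == "shg_table") SHG_REGIONS else OCT_REGIONS
  regions <- unique(records$region)
  regions <- c(intersect(order_ref, regions), setdiff(regions, order_ref))
  if (length(regions) == 0) stop("no region populated")
  rows <- lapply(regions, function(r) {
    sub <- records[records$region == r, , drop = FALSE]
    out <- data.frame(region = r, n = nrow(sub))
    for (f in feats) {
      v <- if (f %in% names(sub)) sub[[f]] else NA_real_
      v <- v[!is.na(v)]
      out[[paste0(f, "_mean")]] <- if (length(v)) mean(v) else NA_real_
      out[[paste0(f, "_sd")]] <- if (length(v) > 1) stats::sd(v) else
        if (length(v) == 1) 0 else NA_real_
    }
    out
  })
  do.call(rbind, rows)
}

#' Write / read a summary table as CSV
#'
#' Plain-CSV serialization of [summarize_tables()] output; reading back
#' reproduces the in-memory summary exactly (values at full precision).
#'
#' @param summary data.frame from [summarize_tables()].
#' @param path output path.
#' @return `path` invisibly; `read_summary` returns the data.frame.
#' @export
write_summary <- function(summary, path) {
  utils::write.csv(format(summary, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_summary
#' @export
read_summary <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$n <- as.integer(df$n)
  df
}
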