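#' SCENITH metabolic dependence and capacity metrics
#'
#' From puromycin MFIs under control, 2-deoxy-glucose (DG), oligomycin (O),
#' and combined (DGO) treatments:
#' * `mito_dependence = 100 * (ctrl - O) / (ctrl - DGO)`
#' * `glucose_dependence = 100 * (ctrl - DG) / (ctrl - DGO)`
#' * `glycolytic_capacity = 100 - mito_dependence`
#' * `faao_capacity = 100 - glucose_dependence` (fatty-acid and amino-acid
#'   oxidation)
#'
#' Values outside \[0, 100\] are clamped with an audit flag; optionally the
#' whole group is shifted so its minimum is 0 before clamping
#' (`adjust = "group_shift"`), preserving within-group differences when a
#' single sample goes negative.
#'
#' @param scenith Tibble with columns `MFI_ctrl`, `MFI_DG`, `MFI_O`,
#'   `MFI_DGO` (one row per sample; other columns are carried through).
#' @param adjust `"clamp"` (default) or `"group_shift"` (requires a `group`
#'   column).
#' @return Input tibble with `mito_dependence`, `glucose_dependence`,
#'   `glycolytic_capacity`, `faao_capacity`, and `clamped` columns.
#' @details Rows with `MFI_ctrl <= MFI_DGO` are invalid assays and raise an
#'   error: translation under full inhibition must lie below control.
#' @export
scenith_metrics <- function(scenith, adjust = c("clamp", "group_shift")) {
  adjust <- match.arg(adjust)
  assert_columns(scenith, c("MFI_ctrl", "MFI_DG", "MFI_O", "MFI_DGO"), "scenith")
  if (any(scenith$MFI_ctrl <= scenith$MFI_DGO)) {
    abort("invalid assay: MFI_ctrl must exceed MFI_DGO")
  }
  span <- scenith$MFI_ctrl - scenith$MFI_DGO
  mito <- 100 * (scenith$MFI_ctrl - scenith$MFI_O) / span
  gluc <- 100 * (scenith$MFI_ctrl - scenith$MFI_DG) / span
  if (adjust == "group_shift") {
    assert_columns(scenith, "group", "scenith")
    shift_to_zero <- function(v, g) {
      mins <- tapply(v, g, min)
      unname(v - pmin(mins[g], 0))
    }
    mito <- shift_to_zero(mito, scenith$group)
    gluc <- shift_to_zero(gluc, scenith$group)
  }
  clamped <- mito < 0 | mito > 100 | gluc < 0 | gluc > 100
  mito_c <- pmin(pmax(mito, 0), 100)
  gluc_c <- pmin(pmax(gluc, 0), 100)
  scenith |>
    mutate(mito_dependence = mito_c,
           glucose_dependence = gluc_c,
           glycolytic_capacity = 100 - mito_c,
           faao_capacity = 100 - gluc_c,
           clamped = clamped)
}

#' Seahorse glycolysis stress test metrics
#'
#' From an ECAR trace with basal, glucose, oligomycin, and 2-DG phases:
#' * `non_glycolytic`: last ECAR before the glucose injection
#' * `glycolysis`: maximum ECAR after glucose and before oligomycin, minus
#'   non-glycolytic acidification
#' * `glycolytic_capacity`: maximum ECAR after oligomycin and before 2-DG,
#'   minus non-glycolytic acidification
#' * `glycolytic_reserve = glycolytic_capacity - glycolysis`
#'
#' @param trace Tibble with `time` (strictly increasing), `ecar`, and
#'   `phase` (`basal`, `glucose`, `oligomycin`, `2DG`, in that order).
#' @return One-row tibble with the four metrics.
#' @export
seahorse_metrics <- function(trace) {
  assert_columns(trace, c("time", "ecar", "phase"), "trace")
  if (is.unsorted(trace$time, strictly = TRUE)) {
    abort("trace times must be strictly increasing")
  }
  phases <- c("basal", "glucose", "oligomycin", "2DG")
  if (!all(phases %in% trace$phase)) {
    abort(sprintf("trace is missing phase(s): %s",
                  paste(setdiff(phases, trace$phase), collapse = ", ")))
  }
  ord <- match(trace$phase, phases)
  if (is.unsorted(ord)) abort("phases must appear in order basal, glucose, oligomycin, 2DG")
  non_gly <- tail(trace$ecar[trace$phase == "basal"], 1)
  gly <- max(trace$ecar[trace$phase == "glucose"]) - non_gly
  cap <- max(trace$ecar[trace$phase == "oligomycin"]) - non_gly
  tibble(non_glycolytic = non_gly, glycolysis = gly,
         glycolytic_capacity = cap, glycolytic_reserve = cap - gly)
}

#' One-way ANOVA across groups with Holm-adjusted pairwise comparisons
#'
#' Convenience summary used for metabolic metrics: overall F-test plus
#' pairwise t-tests (pooled SD) with Holm adjustment.
#'
#' @param data Tibble with the response and a grouping column.
#' @param value Name of the response column.
#' @param group Name of the grouping column.
#' @return List with `anova` (one-row tibble: F, df, p) and `pairwise`
#'   (tibble of Holm-adjusted pairwise p-values).
#' @export
metabolic_anova <- function(data, value, group = "group") {
  df <- tibble(y = data[[value]], g = factor(data[[group]]))
  if (nlevels(df$g) < 2) abort("need at least 2 groups")
  fit <- aov(y ~ g, data = df)
  s <- summary(fit)[[1]]
  pw <- stats::pairwise.t.test(df$y, df$g, p.adjust.method = "holm")
  pw_tbl <- as_tibble(as.data.frame(as.table(pw$p.value)), .name_repair = "minimal")
  names(pw_tbl) <- c("group1", "group2", "p_holm")
  list(
    anova = tibble(F = s$`F value`[1], df_between = s$Df[1],
                   df_within = s$Df[2], p = s$`Pr(>F)`[1]),
    pairwise = filter(pw_tbl, !is.na(.data$p_holm))
  )
}
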