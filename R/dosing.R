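#' Built-in molecular weights (g/mol)
#'
#' Convenience values for the two chemicals used in the reference exposure
#' experiments; any molecular weight can be passed explicitly instead.
#'
#' @format named numeric vector (g/mol).
#' @export
chemical_mw <- c(rapamycin = 914.17, bendiocarb = 223.23)

#' Plan the serial dilution from DMSO stock to in-well exposure
#'
#' Reproduces the standard two-step scheme for dosing chemicals into
#' egg-laying media: a concentrated stock in 100% DMSO is first diluted with
#' water (default 1:100, giving an intermediate at 10x in 1% DMSO), and a
#' small volume of that intermediate (default 30 uL) is then added to each
#' media-filled well (default 300 uL).
#'
#' The final step is reported in two conventions, never silently mixed:
#' \describe{
#'   \item{nominal}{the bench convention that 30 uL into a 300 uL well is a
#'     10-fold dilution, so the defaults give a final 1x chemical in 0.1%
#'     DMSO;}
#'   \item{exact}{the volumetric factor `added / (added + well)` (30/330 with
#'     the defaults), under which the final concentration is 10/11 of
#'     nominal.}
#' }
#'
#' @param stock_fold stock concentration as a fold of the target in-well
#'   concentration (default 1000).
#' @param stock_dmso_pct DMSO percentage of the stock (default 100).
#' @param step1_ratio first-step dilution ratio as parts stock per parts
#'   total (default 1/100 for "1:100").
#' @param well_media_volume_uL media volume already in the well (default 300).
#' @param added_volume_uL volume of intermediate added per well (default 30).
#' @return an object of class `dilution_plan`: a data.frame with one row per
#'   stage (`stage`, `fold_nominal`, `dmso_pct_nominal`, `fold_exact`,
#'   `dmso_pct_exact`, `convention`).
#' @examples
#' plan_dilution()  # 1000x stock -> 10x in 1% DMSO -> nominal 1x in 0.1% DMSO
#' @export
plan_dilution <- function(stock_fold = 1000, stock_dmso_pct = 100,
                          step1_ratio = 1 / 100,
                          well_media_volume_uL = 300, added_volume_uL = 30) {
  stopifnot(stock_fold > 0, stock_dmso_pct > 0, step1_ratio > 0,
            step1_ratio <= 1, well_media_volume_uL > 0, added_volume_uL > 0)
  inter_fold <- stock_fold * step1_ratio
  inter_dmso <- stock_dmso_pct * step1_ratio
  # nominal well-step factor: added volume relative to the media volume
  f_nom <- added_volume_uL / well_media_volume_uL
  # exact volumetric factor: added relative to the combined volume
  f_exact <- added_volume_uL / (well_media_volume_uL + added_volume_uL)
  plan <- data.frame(
    stage = c("stock", "intermediate", "final"),
    fold_nominal = c(stock_fold, inter_fold, inter_fold * f_nom),
    dmso_pct_nominal = c(stock_dmso_pct, inter_dmso, inter_dmso * f_nom),
    fold_exact = c(stock_fold, inter_fold, inter_fold * f_exact),
    dmso_pct_exact = c(stock_dmso_pct, inter_dmso, inter_dmso * f_exact),
    convention = c("both", "both", "nominal is the bench convention"),
    stringsAsFactors = FALSE
  )
  if (any(diff(plan$fold_nominal) >= 0))
    stop("dilution plan is not strictly decreasing in concentration")
  class(plan) <- c("dilution_plan", "data.frame")
  plan
}

#' @export
print.dilution_plan <- function(x, ...) {
  cat("<dilution_plan>\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Estimated daily dietary chemical intake
#'
#' Converts a chemical concentration in the egg-laying media to the mass an
#' adult fly ingests per day, assuming a fixed daily consumption of food and
#' water (about 1.5 uL/day for an adult):
#' \deqn{intake_{ng/day} = conc_{\mu M} \times MW_{g/mol} \times
#'       consumption_{\mu L/day} \times 10^{-3}}
#' Intake is exactly linear in each factor.
#'
#' @param conc_uM media concentration in micromolar (> 0, vectorized).
#' @param mw_g_per_mol molecular weight in g/mol, or a chemical name present
#'   in [chemical_mw].
#' @param consumption_uL daily consumption in uL (default 1.5). Zero is
#'   rejected unless `allow_zero = TRUE`.
#' @param allow_zero permit zero consumption/concentration (returns 0).
#' @return intake in ng/day (full precision; see [format_intake()] for the
#'   conventional display rounding).
#' @examples
#' intake_ng_per_day(25, "rapamycin")        # ~34.3 ng/day
#' intake_ng_per_day(0.1, 914.17)            # ~0.14 ng/day
#' @export
intake_ng_per_day <- function(conc_uM, mw_g_per_mol, consumption_uL = 1.5,
                              allow_zero = FALSE) {
  if (is.character(mw_g_per_mol)) {
    if (!mw_g_per_mol %in% names(chemical_mw))
      stop("unknown chemical '", mw_g_per_mol, "'; pass a molecular weight")
    mw_g_per_mol <- chemical_mw[[mw_g_per_mol]]
  }
  lo <- if (allow_zero) 0 else .Machine$double.xmin
  if (any(conc_uM < lo) || any(mw_g_per_mol < lo) || any(consumption_uL < lo))
    stop("concentration, molecular weight and consumption must be positive")
  conc_uM * mw_g_per_mol * consumption_uL * 1e-3
}

#' Display rounding for intake values
#'
#' Intakes below 1 ng/day are shown to 2 decimal places and larger ones to 1,
#' matching how daily doses are conventionally reported.
#'
#' @param intake numeric ng/day values.
#' @return numeric vector rounded for display.
#' @export
format_intake <- function(intake) {
  ifelse(intake < 1, round(intake, 2), round(intake, 1))
}

#' Batch intake estimates from a CSV of chemicals
#'
#' Reads rows of (`chemical`, `mw_g_per_mol`, `conc_uM`) and appends
#' `intake_ng_day` (full precision) and `intake_display` columns.
#'
#' @param path input CSV; `out` optional output CSV.
#' @param consumption_uL daily consumption passed to [intake_ng_per_day()].
#' @param out optional path to write the augmented table.
#' @return the augmented data.frame.
#' @export
intake_table <- function(path, consumption_uL = 1.5, out = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("chemical", "mw_g_per_mol", "conc_uM")
  if (!all(need %in% names(df)))
    stop("intake CSV needs columns: ", paste(need, collapse = ", "))
  df$intake_ng_day <- intake_ng_per_day(df$conc_uM, df$mw_g_per_mol,
                                        consumption_uL)
  df$intake_display <- format_intake(df$intake_ng_day)
  if (!is.null(out)) write.csv(df, out, row.names = FALSE)
  df
}
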