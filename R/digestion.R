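# Deterministic bench arithmetic for the modified INFOGEST static in vitro
# digestion: fluid recipes, per-phase volume schedule, enzyme dosing by
# activity, and TFA quench volumes. Densities are taken as 1 g/mL throughout,
# matching the protocol's own worked examples.

#' Simulated digestive fluid recipes
#'
#' Electrolyte stocks (at 1.25x working strength), working pH, enzyme
#' activities at working strength and working CaCl2 concentration for the
#' oral, gastric and intestinal phases.
#'
#' @return Named list (`oral`, `gastric`, `intestinal`); each element holds
#'   `stock` (constituent mmol/L at 1.25x), `ph`, `cacl2_mmol_l` and
#'   `enzymes` (`data.frame`: `enzyme`, `activity_u_per_ml`,
#'   `stock_u_per_ml`).
#' @export
fluid_recipes <- function() {
  stocks <- utils::read.csv(pkg_extdata("fluid_stocks.csv"),
                            comment.char = "#", stringsAsFactors = FALSE)
  enz <- utils::read.csv(pkg_extdata("fluid_enzymes.csv"),
                         comment.char = "#", stringsAsFactors = FALSE)
  phases <- c("oral", "gastric", "intestinal")
  out <- lapply(phases, function(ph) {
    e <- enz[enz$phase == ph, , drop = FALSE]
    list(phase = ph,
         stock = stats::setNames(stocks[[ph]], stocks$constituent),
         ph = unique(e$ph),
         cacl2_mmol_l = unique(e$cacl2_mmol_l),
         enzymes = e[, c("enzyme", "activity_u_per_ml", "stock_u_per_ml")])
  })
  stats::setNames(out, phases)
}

#' Digestion volume schedule
#'
#' Computes the rehydration water and per-phase simulated-fluid volumes for a
#' given dry sample mass, with gastric-phase sampling losses carried into the
#' intestinal addition. The default `"bolus"` mode reproduces the protocol's
#' worked examples: oral fluid 1:1 v/w with the dry mass; gastric fluid 1:1
#' with the bread + oral bolus (rehydration water excluded); intestinal fluid
#' 1:1 with the total after gastric addition, minus any volume removed during
#' the gastric phase. `"literal"` mode instead reads "total solution" as every
#' liquid added so far, rehydration water included.
#'
#' @param dry_mass Freeze-dried sample mass (g), `> 0`.
#' @param gastric_aliquots Volumes (mL) removed as time points during the
#'   gastric phase.
#' @param aliquot_ml Aliquot volume (mL) used for the per-time-point TFA
#'   quench table.
#' @param mode `"bolus"` (worked-example interpretation, default) or
#'   `"literal"`.
#' @return Object of class `digestion_plan`: water, oral, gastric and
#'   intestinal volumes (mL), the sampling-loss ledger, the TFA quench volume
#'   per aliquot (uL of 12 percent stock to reach 0.1 percent) and the fluid
#'   recipes.
#' @export
#' @examples
#' volume_schedule(1.25) # water 4, oral 1.25, gastric 2.5, intestinal 5 mL
volume_schedule <- function(dry_mass, gastric_aliquots = numeric(),
                            aliquot_ml = 1, mode = c("bolus", "literal")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(dry_mass), length(dry_mass) == 1L, dry_mass > 0)
  if (length(gastric_aliquots) && any(gastric_aliquots <= 0)) {
    stop("gastric aliquot volumes must be positive", call. = FALSE)
  }
  water <- dry_mass * 4 / 1.25      # 1.25:4 w/v rehydration
  oral <- dry_mass * 1              # 1:1 v/w with the dry mass
  base <- if (mode == "bolus") dry_mass + oral else water + dry_mass + oral
  gastric <- base
  gastric_total <- base + gastric
  removed <- sum(gastric_aliquots)
  if (removed >= gastric_total) {
    stop(sprintf("aliquots (%.3g mL) exceed the gastric-phase volume (%.3g mL)",
                 removed, gastric_total), call. = FALSE)
  }
  intestinal <- gastric_total - removed
  structure(list(dry_mass = dry_mass, mode = mode,
                 water_ml = water, oral_ml = oral, gastric_ml = gastric,
                 intestinal_ml = intestinal,
                 gastric_aliquots_ml = gastric_aliquots,
                 sampling_loss_ml = removed,
                 aliquot_ml = aliquot_ml,
                 quench_ul = quench_volume(aliquot_ml),
                 recipes = fluid_recipes()),
            class = "digestion_plan")
}

#' @export
print.digestion_plan <- function(x, ...) {
  cat(sprintf("INFOGEST digestion plan (%s mode) for %.3g g dry sample\n",
              x$mode, x$dry_mass))
  cat(sprintf("  rehydration water : %8.3f mL\n", x$water_ml))
  cat(sprintf("  oral fluid        : %8.3f mL\n", x$oral_ml))
  cat(sprintf("  gastric fluid     : %8.3f mL\n", x$gastric_ml))
  if (x$sampling_loss_ml > 0) {
    cat(sprintf("  gastric sampling  : %8.3f mL removed\n", x$sampling_loss_ml))
  }
  cat(sprintf("  intestinal fluid  : %8.3f mL\n", x$intestinal_ml))
  cat(sprintf("  TFA quench        : %8.2f uL of 12%% stock per %.3g mL aliquot (-> 0.1%%)\n",
              x$quench_ul, x$aliquot_ml))
  invisible(x)
}

#' TFA quench volume
#'
#' Volume of acid stock to add to an aliquot so the final mixture holds the
#' target v/v percentage: `v = aliquot_uL * target / (stock - target)`.
#'
#' @param aliquot_ml Aliquot volume (mL).
#' @param stock_percent Stock strength (percent v/v), default 12.
#' @param target_percent Final strength (percent v/v), default 0.1; must be
#'   `< stock_percent`.
#' @return Stock volume to add, in uL.
#' @export
#' @examples
#' quench_volume(1) # 8.40 uL
quench_volume <- function(aliquot_ml, stock_percent = 12,
                          target_percent = 0.1) {
  stopifnot(is.numeric(aliquot_ml), all(aliquot_ml > 0),
            stock_percent > 0, target_percent >= 0)
  if (target_percent >= stock_percent) {
    stop("target percentage must be below the stock percentage", call. = FALSE)
  }
  aliquot_ml * 1000 * target_percent / (stock_percent - target_percent)
}

#' Working-strength fluid preparation
#'
#' Allocates a requested final volume of a 1x working digestion fluid:
#' `final_volume / 1.25` of the 1.25x electrolyte stock, CaCl2 from a
#' concentrated stock, enzyme solution dosed by activity, and water to
#' volume. Component volumes sum exactly to the requested volume.
#'
#' @param phase `"oral"`, `"gastric"` or `"intestinal"`.
#' @param final_volume Working fluid volume required (mL), `> 0`.
#' @param include_enzymes Set `FALSE` for an enzyme-free fluid (blanks).
#' @param cacl2_stock_mmol_l CaCl2 stock concentration (mmol/L), default 300.
#' @param recipes Fluid recipes, default [fluid_recipes()].
#' @return List with `components` (`data.frame`: `component`, `volume_ml`)
#'   and `enzyme_units` (named total activity units in the final fluid).
#' @export
#' @examples
#' working_fluid("gastric", 10) # 8 mL stock; 20,000 U pepsin in total
working_fluid <- function(phase = c("oral", "gastric", "intestinal"),
                          final_volume, include_enzymes = TRUE,
                          cacl2_stock_mmol_l = 300, recipes = fluid_recipes()) {
  phase <- match.arg(phase)
  stopifnot(is.numeric(final_volume), length(final_volume) == 1L,
            final_volume > 0)
  r <- recipes[[phase]]
  stock_ml <- final_volume / 1.25
  cacl2_ml <- final_volume * r$cacl2_mmol_l / cacl2_stock_mmol_l
  enz <- r$enzymes
  if (include_enzymes && nrow(enz)) {
    enz_ml <- final_volume * enz$activity_u_per_ml / enz$stock_u_per_ml
    units <- stats::setNames(final_volume * enz$activity_u_per_ml, enz$enzyme)
  } else {
    enz <- enz[0, , drop = FALSE]
    enz_ml <- numeric()
    units <- stats::setNames(numeric(), character())
  }
  water_ml <- final_volume - stock_ml - cacl2_ml - sum(enz_ml)
  if (water_ml < 0) {
    stop("component volumes exceed the requested final volume; use more concentrated stocks",
         call. = FALSE)
  }
  components <- data.frame(
    component = c("electrolyte stock (1.25x)", "CaCl2 stock",
                  if (nrow(enz)) paste0(enz$enzyme, " stock"), "water"),
    volume_ml = c(stock_ml, cacl2_ml, enz_ml, water_ml),
    stringsAsFactors = FALSE)
  list(phase = phase, final_volume_ml = final_volume,
       components = components, enzyme_units = units)
}
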