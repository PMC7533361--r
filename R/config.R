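# Configuration loading, the shipped default config, and cross-validation of
# the configured transition list against recomputation from the sequences.

#' Shipped peptide and epitope configuration
#'
#' `default_peptides()` returns the marker peptides P1--P6 plus the heavy
#' internal standard P1H as [peptide()] objects; `default_epitopes()` the
#' DQ2.5 glia-alpha 9-mer epitope cores. Both are read from editable CSV
#' files under `inst/extdata`.
#'
#' @param path Optional directory holding `peptides.csv` / `epitopes.csv`;
#'   default the shipped files.
#' @return Named list of peptides; or a `data.frame` (`epitope`, `core`).
#' @export
#' @examples
#' names(default_peptides())
default_peptides <- function(path = NULL) {
  file <- if (is.null(path)) pkg_extdata("peptides.csv") else
    file.path(path, "peptides.csv")
  tab <- utils::read.csv(file, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("name", "sequence", "charges", "label_position", "label_13c",
            "label_15n", "label_delta", "rt_min")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop(sprintf("peptide config %s lacks column(s): %s", file,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (!nrow(tab)) stop("peptide config is empty", call. = FALSE)
  peps <- lapply(seq_len(nrow(tab)), function(i) {
    lab <- NULL
    if (!is.na(tab$label_position[i])) {
      delta <- if (is.na(tab$label_delta[i])) NULL else tab$label_delta[i]
      lab <- isotope_label(tab$label_position[i],
                           c13 = ifelse(is.na(tab$label_13c[i]), 0,
                                        tab$label_13c[i]),
                           n15 = ifelse(is.na(tab$label_15n[i]), 0,
                                        tab$label_15n[i]),
                           delta = delta)
    }
    charges <- as.integer(strsplit(as.character(tab$charges[i]), ";")[[1]])
    peptide(tab$name[i], tab$sequence[i], charges = charges, label = lab,
            rt = tab$rt_min[i])
  })
  stats::setNames(peps, tab$name)
}

#' @rdname default_peptides
#' @export
default_epitopes <- function(path = NULL) {
  file <- if (is.null(path)) pkg_extdata("epitopes.csv") else
    file.path(path, "epitopes.csv")
  tab <- utils::read.csv(file, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("epitope", "core") %in% names(tab)))
  if (any(nchar(tab$core) != 9L)) {
    stop("epitope cores must be 9 residues long", call. = FALSE)
  }
  tab
}

#' Load a toolkit configuration
#'
#' Reads the peptide table, epitope cores, transition list, gradient,
#' instrument parameters and fluid recipes from a config directory (the
#' shipped defaults when `path` is `NULL`) into one validated object.
#'
#' @param path Config directory, or `NULL` for the shipped default.
#' @param options Named list overriding quantification options
#'   (`precursor_tol`, `fragment_tol`, `dilution_factor`, `blank_k`,
#'   `cal_levels`, `lodloq_levels`, `window_half_width`, `run_end`).
#' @param seed Integer seed recorded in the config and used by pipeline runs.
#' @return Object of class `prm_config`.
#' @export
load_config <- function(path = NULL, options = list(), seed = 1L) {
  if (!is.null(path) && !dir.exists(path)) {
    stop(sprintf("config directory '%s' does not exist", path), call. = FALSE)
  }
  rd <- function(f) if (is.null(path)) pkg_extdata(f) else file.path(path, f)
  defaults <- list(precursor_tol = 0.005, fragment_tol = 0.01,
                   dilution_factor = 2.1, blank_k = 10,
                   cal_levels = c(0.5, 1, 2, 5, 10),
                   lodloq_levels = c(10, 5, 2, 1, 0.5, 0.3, 0.1, 0.05, 0.03,
                                     0.01),
                   window_half_width = 0.5, run_end = 15.07)
  opts <- utils::modifyList(defaults, options)
  gradient <- utils::read.csv(rd("gradient.csv"), comment.char = "#",
                              stringsAsFactors = FALSE)
  structure(list(
    peptides = default_peptides(path),
    epitopes = default_epitopes(path),
    transitions = read_transitions(rd("transitions.csv")),
    gradient = gradient,
    instrument = utils::read.csv(rd("instrument.csv"), comment.char = "#",
                                 stringsAsFactors = FALSE),
    fluids = fluid_recipes(),
    options = opts,
    seed = as.integer(seed)),
    class = "prm_config")
}

#' Save a configuration back to CSV files
#'
#' Writes the peptide, epitope and transition tables of a config to a
#' directory in the same format [load_config()] reads, so that
#' load -> save -> load is an identity for those tables.
#'
#' @param config A `prm_config`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
save_config <- function(config, dir) {
  stopifnot(inherits(config, "prm_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  peps <- config$peptides
  tab <- do.call(rbind, lapply(peps, function(p) {
    lab <- p$label
    data.frame(name = p$name, sequence = p$sequence,
               charges = paste(p$charges, collapse = ";"),
               label_position = if (is.null(lab)) NA else lab$position,
               label_13c = if (is.null(lab)) NA else lab$c13,
               label_15n = if (is.null(lab)) NA else lab$n15,
               label_delta = if (is.null(lab) || is.null(lab$delta)) NA else
                 lab$delta,
               rt_min = p$rt, stringsAsFactors = FALSE)
  }))
  utils::write.csv(tab, file.path(dir, "peptides.csv"), row.names = FALSE,
                   quote = FALSE, na = "")
  utils::write.csv(config$epitopes, file.path(dir, "epitopes.csv"),
                   row.names = FALSE, quote = FALSE)
  write_transitions(config$transitions, file.path(dir, "transitions.csv"))
  utils::write.csv(config$gradient, file.path(dir, "gradient.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  utils::write.csv(config$instrument, file.path(dir, "instrument.csv"),
                   row.names = FALSE, quote = FALSE)
  for (f in c("fluid_stocks.csv", "fluid_enzymes.csv")) {
    file.copy(pkg_extdata(f), file.path(dir, f), overwrite = TRUE)
  }
  invisible(dir)
}

#' Validate a configured transition list against recomputation
#'
#' Every configured precursor and labelled fragment m/z is recomputed from
#' the peptide sequences (isotope labels included) and compared at the
#' configured tolerances (`precursor_tol`, default 0.005 Th;
#' `fragment_tol`, default 0.01 Th). Discrepancies are reported, never
#' silently corrected:
#'
#' * `precursor`: configured precursor off by more than the tolerance; when
#'   two peptides' values cross-match, the note records the apparent swap.
#' * `fragment_relabel`: the printed m/z matches a different ion of the same
#'   peptide (e.g. a "b9" that is actually b8).
#' * `fragment_mismatch` / `fragment_unassigned`: the printed m/z matches the
#'   stated ion poorly, or no b/y/a ion at all.
#' * `label_delta`: a configured explicit label-delta override that differs
#'   from the composition-derived delta.
#'
#' @param config A `prm_config` from [load_config()].
#' @return `data.frame` of class `prm_validation`: `type`, `peptide`, `item`,
#'   `printed`, `computed`, `delta`, `note`; zero rows when everything
#'   recomputes.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "prm_config"))
  tr <- config$transitions
  if (!nrow(tr)) stop("config holds no transitions", call. = FALSE)
  ptol <- config$options$precursor_tol
  ftol <- config$options$fragment_tol
  rows <- list()
  add <- function(type, pep, item, printed, computed, note = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      type = type, peptide = pep, item = item, printed = printed,
      computed = computed, delta = printed - computed, note = note,
      stringsAsFactors = FALSE)
  }

  # --- precursors ---------------------------------------------------------
  prec <- unique(tr[, c("peptide", "precursor_mz", "charge")])
  prec$computed <- NA_real_
  for (i in seq_len(nrow(prec))) {
    p <- config$peptides[[prec$peptide[i]]]
    if (is.null(p)) {
      add("unknown_peptide", prec$peptide[i], "precursor",
          prec$precursor_mz[i], NA_real_, "peptide not in config")
      next
    }
    prec$computed[i] <- precursor_mz(p, prec$charge[i])
  }
  bad <- which(!is.na(prec$computed) &
                 abs(prec$precursor_mz - prec$computed) > ptol)
  for (i in bad) {
    # swap detection: does this printed value match another peptide's
    # recomputed precursor (and vice versa)?
    note <- ""
    for (j in setdiff(bad, i)) {
      if (abs(prec$precursor_mz[i] - prec$computed[j]) <= 4 * ptol &&
          abs(prec$precursor_mz[j] - prec$computed[i]) <= 4 * ptol) {
        note <- sprintf("apparently swapped with %s", prec$peptide[j])
      }
    }
    add("precursor", prec$peptide[i],
        sprintf("precursor (%d+)", prec$charge[i]),
        prec$precursor_mz[i], prec$computed[i], note)
  }

  # --- fragments ----------------------------------------------------------
  frag <- tr[!is.na(tr$fragment_mz), , drop = FALSE]
  for (i in seq_len(nrow(frag))) {
    p <- config$peptides[[frag$peptide[i]]]
    if (is.null(p)) next
    zmax <- max(frag$charge[i], 1L)
    base <- fragment_table(p, max_charge = 1L)[, c("series", "ordinal")]
    theo <- do.call(rbind, lapply(seq_len(zmax), function(z) {
      g <- base
      g$charge <- z
      g
    }))
    theo$mz <- mapply(function(s, o, z) fragment_mz(p, s, o, z),
                      theo$series, theo$ordinal, theo$charge)
    printed <- frag$fragment_mz[i]
    lab <- frag$fragment_label[i]
    m <- regmatches(lab, regexec("^([aby])([0-9]+)\\*?$", lab))[[1]]
    own <- NA_real_
    if (length(m) == 3L) {
      ord <- as.integer(m[3])
      if (ord >= 1L && ord < length(p$residues)) {
        own_all <- vapply(seq_len(zmax), function(z)
          fragment_mz(p, m[2], ord, z), numeric(1))
        own <- own_all[which.min(abs(own_all - printed))]
      }
    }
    if (!is.na(own) && abs(printed - own) <= ftol) next
    d <- abs(theo$mz - printed)
    near <- which.min(d)
    if (d[near] <= ftol) {
      add("fragment_relabel", frag$peptide[i], lab, printed, theo$mz[near],
          sprintf("matches %s%d (%d+)", theo$series[near],
                  theo$ordinal[near], theo$charge[near]))
    } else if (!is.na(own) && abs(printed - own) <= 0.5) {
      add("fragment_mismatch", frag$peptide[i], lab, printed, own,
          sprintf("off by %.4f Th from computed %s", printed - own, lab))
    } else {
      add("fragment_unassigned", frag$peptide[i], lab, printed, theo$mz[near],
          sprintf("no b/y/a ion within %.3g Th (nearest %s%d (%d+), off %.4f)",
                  ftol, theo$series[near], theo$ordinal[near],
                  theo$charge[near], printed - theo$mz[near]))
    }
  }

  # --- isotope labels -----------------------------------------------------
  for (p in config$peptides) {
    lab <- p$label
    if (is.null(lab) || is.null(lab$delta)) next
    comp <- lab$c13 * .CONSTANTS[["c13_delta"]] +
      lab$n15 * .CONSTANTS[["n15_delta"]]
    if (abs(lab$delta - comp) > 0.01) {
      add("label_delta", p$name, sprintf("label @%d", lab$position),
          lab$delta, comp,
          sprintf("override %+.4f Da differs from composition %+.4f Da",
                  lab$delta, comp))
    }
  }

  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(type = character(), peptide = character(), item = character(),
               printed = numeric(), computed = numeric(), delta = numeric(),
               note = character(), stringsAsFactors = FALSE)
  out <- out[order(out$peptide, out$type, out$item), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("prm_validation", class(out))
  out
}

#' @export
print.prm_validation <- function(x, ...) {
  if (!nrow(x)) {
    cat("transition list fully consistent with recomputation\n")
    return(invisible(x))
  }
  cat(sprintf("%d discrepancy(ies) between configured and recomputed values:\n",
              nrow(x)))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  [%s] %s %s: printed %.4f vs computed %.4f  %s\n",
                x$type[i], x$peptide[i], x$item[i], x$printed[i],
                x$computed[i], x$note[i]))
  }
  invisible(x)
}
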