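# Per-MIE dysregulated-target counting at the +/-0.6 log2FC threshold and
# Table-1-style condition profiles.

#' Count dysregulated targets per MIE for one condition
#'
#' For each MIE, counts its mapped targets with log2fc >= `upThr` (up) or
#' <= `downThr` (down); both boundaries are inclusive. Targets missing from
#' `fc` contribute nothing. Regulation mode is ignored by default;
#' `modeAware = TRUE` counts only targets whose direction is concordant with
#' the edge mode (Activation up / Repression down; Unknown edges count
#' either way).
#'
#' @param fc named numeric of per-gene log2 fold changes for one condition.
#' @param network an [MIENetwork-class].
#' @param upThr,downThr thresholds; `upThr` must exceed `downThr`.
#' @param modeAware count only mode-concordant dysregulation (default
#'   FALSE).
#' @return data.frame per MIE: `mie`, `n_up`, `n_down`, `n_total`, with
#'   list-columns `genes_up` and `genes_down`.
#' @examples
#' net <- buildMIENetwork(
#'   data.frame(tf = "TF1", target = c("A", "B", "C"), mode = "Unknown"),
#'   data.frame(name = "TF1"), expressionGenes = c("A", "B", "C"))
#' countDysregulated(c(A = 0.6, B = -0.6, C = 0.59), net)
#' @export
countDysregulated <- function(fc, network, upThr = 0.6, downThr = -0.6,
                              modeAware = FALSE) {
  stopifnot(is(network, "MIENetwork"))
  if (upThr <= downThr)
    stopf("upThr (%g) must be greater than downThr (%g)", upThr, downThr)
  ed <- mieEdges(network)
  res <- lapply(mieNames(network), function(m) {
    sub <- ed[ed$mie == m, , drop = FALSE]
    sub <- sub[sub$target %in% names(fc), , drop = FALSE]
    # per-target mode: distinct targets; a target with several modes keeps
    # the permissive Unknown for mode-aware counting
    tg <- unique(sub$target)
    val <- fc[tg]
    up <- !is.na(val) & val >= upThr
    down <- !is.na(val) & val <= downThr
    if (modeAware && length(tg)) {
      md <- vapply(tg, function(t) {
        mm <- unique(sub$mode[sub$target == t])
        if (length(mm) > 1L) "Unknown" else mm
      }, character(1))
      up <- up & md %in% c("Activation", "Unknown")
      down <- down & md %in% c("Repression", "Unknown")
    }
    data.frame(mie = m, n_up = sum(up), n_down = sum(down),
               n_total = sum(up) + sum(down),
               genes_up = I(list(sort(tg[up]))),
               genes_down = I(list(sort(tg[down]))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Profile dysregulated-target counts across conditions
#'
#' Applies [countDysregulated()] to every requested (chemical, dose, sex)
#' condition of a fold-change table.
#'
#' @param fcTable data.frame as from [buildFCTable()].
#' @param network an [MIENetwork-class].
#' @param conditions data.frame with `chemical`, `dose_mg_per_kg`, `sex`
#'   (default: all conditions in `fcTable`). A requested condition absent
#'   from the table is an error.
#' @param upThr,downThr,modeAware passed to [countDysregulated()].
#' @return Long data.frame: `mie`, `chemical`, `class`, `sex`,
#'   `dose_mg_per_kg`, `n_up`, `n_down`, `n_total`.
#' @export
profileConditions <- function(fcTable, network, conditions = NULL,
                              upThr = 0.6, downThr = -0.6,
                              modeAware = FALSE) {
  have <- unique(fcTable[, c("chemical", "class", "dose_mg_per_kg", "sex")])
  if (is.null(conditions)) conditions <- have
  rows <- vector("list", nrow(conditions))
  for (i in seq_len(nrow(conditions))) {
    cc <- conditions[i, ]
    sel <- fcTable$chemical == cc$chemical &
      fcTable$dose_mg_per_kg == cc$dose_mg_per_kg & fcTable$sex == cc$sex
    if (!any(sel))
      stopf("condition %s / %g mg/kg / %s absent from the fold-change table",
            cc$chemical, cc$dose_mg_per_kg, cc$sex)
    fc <- stats::setNames(fcTable$log2fc[sel], fcTable$gene[sel])
    cnt <- countDysregulated(fc, network, upThr, downThr, modeAware)
    rows[[i]] <- data.frame(
      mie = cnt$mie, chemical = cc$chemical,
      class = fcTable$class[sel][1], sex = cc$sex,
      dose_mg_per_kg = cc$dose_mg_per_kg,
      n_up = cnt$n_up, n_down = cnt$n_down, n_total = cnt$n_total,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Top-dose wide view of a dysregulation profile
#'
#' Restricts a long profile to the `k` highest doses of each (chemical,
#' sex) and pivots to the familiar publication layout: one row per MIE, one
#' `n_total` column per chemical x sex x dose, columns ordered by chemical,
#' then sex, then ascending dose.
#'
#' @param profile long profile from [profileConditions()].
#' @param k doses to keep per (chemical, sex) (default 3).
#' @return Wide data.frame, first column `mie`.
#' @export
profileTopDoses <- function(profile, k = 3L) {
  keep <- do.call(rbind, lapply(
    split(profile, paste(profile$chemical, profile$sex)), function(df) {
      top <- sort(unique(df$dose_mg_per_kg), decreasing = TRUE)
      df[df$dose_mg_per_kg %in% utils::head(top, k), ]
    }))
  keep$colkey <- sprintf("%s|%s|%g", keep$chemical, keep$sex,
                         keep$dose_mg_per_kg)
  ord <- unique(keep[order(keep$chemical, keep$sex, keep$dose_mg_per_kg),
                     "colkey"])
  mies <- unique(profile$mie)
  wide <- data.frame(mie = mies, stringsAsFactors = FALSE)
  for (ck in ord)
    wide[[ck]] <- keep$n_total[keep$colkey == ck][
      match(mies, keep$mie[keep$colkey == ck])]
  wide
}

#' Up/down direction split of a profile
#'
#' Adds `frac_up` and `frac_down` to a long profile. Cells with
#' `n_total = 0` get `NA` fractions and `undefined = TRUE` rather than a
#' 0/0 artefact.
#'
#' @param profile long profile from [profileConditions()].
#' @return The profile with `frac_up`, `frac_down`, `undefined` columns.
#' @export
directionSplit <- function(profile) {
  if (!nrow(profile)) stopf("empty profile")
  undef <- profile$n_total == 0
  profile$frac_up <- ifelse(undef, NA_real_, profile$n_up / profile$n_total)
  profile$frac_down <- ifelse(undef, NA_real_,
                              profile$n_down / profile$n_total)
  profile$undefined <- undef
  profile
}

#' Write a profile to TSV
#'
#' `writeProfileTSV` writes the long layout; `writeProfileTableTSV` writes
#' the top-dose wide layout from [profileTopDoses()].
#'
#' @param profile long profile.
#' @param path file path.
#' @param k top doses per (chemical, sex) for the wide layout.
#' @return Invisibly, `path`.
#' @export
writeProfileTSV <- function(profile, path) writeTSV(profile, path)

#' @rdname writeProfileTSV
#' @export
writeProfileTableTSV <- function(profile, path, k = 3L) {
  writeTSV(profileTopDoses(profile, k), path)
}
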