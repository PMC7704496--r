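#' Default atom weights for combined chemical-shift perturbations
#'
#' Dimensionless scaling factors applied to per-atom shift changes before
#' taking the Euclidean norm. Proton shifts carry weight 1; nitrogen-15
#' shifts are scaled by 0.14, the conventional amide-nitrogen factor that
#' compensates the wider 15N shift dispersion. Side-chain amides (tryptophan
#' indole Hε1/Nε1, glutamine/asparagine NH2 groups) use the same
#' nucleus-based weights. Override any entry, or supply your own named
#' vector, wherever a `weights` argument is accepted.
#'
#' @param h_weight weight for 1H shifts.
#' @param n_weight weight for 15N shifts.
#' @return named numeric vector of weights keyed by PDB-style atom name.
#' @examples
#' shift_weights()[c("H", "N", "HE1", "NE1")]
#' @export
shift_weights <- function(h_weight = 1, n_weight = 0.14) {
  .check_nonneg(h_weight, "h_weight")
  .check_nonneg(n_weight, "n_weight")
  c(H = h_weight, N = n_weight,
    HE1 = h_weight, NE1 = n_weight,
    HE21 = h_weight, HE22 = h_weight, NE2 = n_weight,
    HD21 = h_weight, HD22 = h_weight, ND2 = n_weight)
}

#' Combined chemical-shift perturbation of one residue
#'
#' Weighted Euclidean norm of the per-atom shift changes between the free
#' and bound states:
#' \deqn{\Delta\delta_{comb} = \sqrt{\sum_i (w_i \, \Delta\delta_i)^2}.}
#' Any set of atoms can contribute (backbone H/N, tryptophan indole
#' Hε1/Nε1, glutamine side-chain amides, ...); each present atom must have
#' a weight.
#'
#' @param atom_deltas named numeric vector of shift changes (ppm), names are
#'   atom labels.
#' @param weights named numeric vector of weights; see [shift_weights()].
#' @return the combined shift change (ppm, >= 0).
#' @examples
#' combined_shift(c(H = 0.10, N = 0.50)) # sqrt(0.01 + 0.0049)
#' @export
combined_shift <- function(atom_deltas, weights = shift_weights()) {
  if (length(atom_deltas) == 0L)
    stop_invalid("at least one atom shift change is required")
  .check_finite(atom_deltas, "atom_deltas")
  if (is.null(names(atom_deltas)) || any(names(atom_deltas) == ""))
    stop_invalid("'atom_deltas' must be a named vector of atom labels")
  missing_w <- setdiff(names(atom_deltas), names(weights))
  if (length(missing_w))
    stop_config("no weight defined for atom(s): %s",
                paste(missing_w, collapse = ", "))
  w <- weights[names(atom_deltas)]
  sqrt(sum((w * atom_deltas)^2))
}

#' Per-residue perturbation profile from endpoint peak lists
#'
#' Compares a free-protein peak list with the endpoint of a titration
#' (protein saturated with ligand) and computes, per residue, the combined
#' chemical-shift perturbation over all atoms observed in both states.
#' Residues observed free but entirely absent from the bound list are
#' flagged `disappeared` (intermediate exchange broadened them beyond
#' detection, or the bound resonance could not be identified); residues
#' absent from both lists (prolines, unassigned) are `not-evaluable`.
#'
#' @param free_peaks,bound_peaks peak-list data.frames with columns
#'   `residue_index`, `residue_code`, `atom`, `shift_ppm`
#'   (see [read_peak_list()]).
#' @param weights atom weights, see [shift_weights()].
#' @param residues optional integer vector giving the full residue index
#'   space (defaults to `1:max(index)` over both lists), so that
#'   unobserved residues appear as `not-evaluable` rows.
#' @return a `perturbation_profile` data.frame with columns
#'   `residue_index`, `residue_code`, `delta_comb`, `status`.
#' @seealso [classify_residues()], [sigma0()]
#' @export
perturbation_profile <- function(free_peaks, bound_peaks,
                                 weights = shift_weights(),
                                 residues = NULL) {
  free_peaks <- validate_peak_list(free_peaks)
  bound_peaks <- validate_peak_list(bound_peaks)
  if (is.null(residues))
    residues <- seq_len(max(free_peaks$residue_index,
                            bound_peaks$residue_index))
  code_of <- function(i) {
    cc <- c(free_peaks$residue_code[free_peaks$residue_index == i],
            bound_peaks$residue_code[bound_peaks$residue_index == i])
    if (length(cc)) cc[1] else NA_character_
  }
  rows <- lapply(residues, function(i) {
    fr <- free_peaks[free_peaks$residue_index == i, , drop = FALSE]
    bd <- bound_peaks[bound_peaks$residue_index == i, , drop = FALSE]
    if (nrow(fr) == 0L && nrow(bd) == 0L)
      return(data.frame(residue_index = i, residue_code = code_of(i),
                        delta_comb = NA_real_, status = "not-evaluable"))
    if (nrow(fr) == 0L) # bound-only peak: no free reference shift
      return(data.frame(residue_index = i, residue_code = code_of(i),
                        delta_comb = NA_real_, status = "not-evaluable"))
    if (nrow(bd) == 0L)
      return(data.frame(residue_index = i, residue_code = code_of(i),
                        delta_comb = NA_real_, status = "disappeared"))
    common <- intersect(fr$atom, bd$atom)
    if (length(common) == 0L)
      return(data.frame(residue_index = i, residue_code = code_of(i),
                        delta_comb = NA_real_, status = "disappeared"))
    deltas <- stats::setNames(
      bd$shift_ppm[match(common, bd$atom)] -
        fr$shift_ppm[match(common, fr$atom)],
      common)
    data.frame(residue_index = i, residue_code = code_of(i),
               delta_comb = combined_shift(deltas, weights),
               status = "measured")
  })
  out <- do.call(rbind, rows)
  class(out) <- c("perturbation_profile", "data.frame")
  out
}

#' Perturbation threshold sigma0
#'
#' Population standard deviation of the combined shift changes over the
#' measured residues only. Disappeared residues are excluded here (their
#' imputed value would otherwise feed back into the threshold that defines
#' it) and imputed afterwards by [classify_residues()].
#'
#' @param profile a `perturbation_profile`.
#' @return sigma0 in ppm.
#' @export
sigma0 <- function(profile) {
  x <- profile$delta_comb[profile$status == "measured"]
  if (length(x) < 3L)
    stop_invalid("at least 3 measured residues are required to estimate sigma0 (got %d)",
                 length(x))
  sqrt(mean((x - mean(x))^2))
}

.csp_classes <- c("none", "moderate", "high", "disappeared-high",
                  "not-evaluable")

#' Classify residues into interaction-probability classes
#'
#' Threshold classification of a perturbation profile against `sigma0`:
#' measured residues with `delta_comb < sigma0` are `none`, in
#' `[sigma0, 2*sigma0)` `moderate` (moderately probable interaction), and
#' `>= 2*sigma0` `high` (very probable interaction). Residues whose bound
#' resonance disappeared are assigned the imputed value `2*sigma0` and the
#' class `disappeared-high`; prolines/unassigned stay `not-evaluable`.
#'
#' @param profile a `perturbation_profile`.
#' @param s0 the threshold; computed by [sigma0()] from the measured
#'   residues when omitted.
#' @param ligand_label optional label (e.g. the oligonucleotide) carried in
#'   the result.
#' @return an `epitope_map`: the profile with `delta_comb` imputed for
#'   disappeared residues and a `class` column; attributes `sigma0` and
#'   `ligand_label`.
#' @examples
#' free <- data.frame(residue_index = 1:4, residue_code = "X",
#'                    atom = "H", shift_ppm = c(8, 8, 8, 8))
#' bound <- data.frame(residue_index = 1:4, residue_code = "X",
#'                     atom = "H", shift_ppm = c(8.01, 8.02, 7.99, 8.40))
#' classify_residues(perturbation_profile(free, bound))
#' @export
classify_residues <- function(profile, s0 = NULL, ligand_label = NA_character_) {
  if (is.null(s0)) s0 <- sigma0(profile)
  .check_pos(s0, "s0")
  out <- as.data.frame(profile)
  cls <- character(nrow(out))
  for (i in seq_len(nrow(out))) {
    cls[i] <- switch(out$status[i],
      "not-evaluable" = "not-evaluable",
      "disappeared" = "disappeared-high",
      "measured" = {
        d <- out$delta_comb[i]
        if (d >= 2 * s0) "high" else if (d >= s0) "moderate" else "none"
      })
  }
  out$delta_comb[out$status == "disappeared"] <- 2 * s0
  out$class <- factor(cls, levels = .csp_classes)
  structure(out, class = c("epitope_map", "data.frame"),
            sigma0 = s0, ligand_label = ligand_label)
}

#' @export
print.epitope_map <- function(x, ...) {
  lab <- attr(x, "ligand_label")
  cat(sprintf("Epitope map%s: sigma0 = %.4f ppm, %d residues\n",
              if (is.na(lab)) "" else paste0(" [", lab, "]"),
              attr(x, "sigma0"), nrow(x)))
  print(table(x$class))
  hits <- x$residue_index[x$class %in% c("high", "disappeared-high")]
  if (length(hits))
    cat("high-probability residues:", paste(hits, collapse = ", "), "\n")
  invisible(x)
}

#' Consensus binding epitope across two or more ligands
#'
#' A residue enters the consensus epitope if it has a high interaction
#' probability (`high` or `disappeared-high`) for at least one ligand and
#' at least a moderate probability (`moderate`, `high` or
#' `disappeared-high`) for every other ligand. The rule is symmetric in the
#' order of the maps, and the consensus set is a subset of the union of the
#' high sets.
#'
#' @param maps a list of two or more `epitope_map` objects covering the
#'   same residue index space.
#' @return a data.frame with `residue_index`, `residue_code`, one class
#'   column per map (named after its ligand label where available) and a
#'   logical `in_consensus`.
#' @export
consensus_epitope <- function(maps) {
  if (!is.list(maps) || length(maps) < 2L)
    stop_invalid("'maps' must be a list of >= 2 epitope maps")
  if (!all(vapply(maps, inherits, logical(1), "epitope_map")))
    stop_invalid("every element of 'maps' must be an epitope_map")
  idx <- maps[[1]]$residue_index
  for (m in maps[-1])
    if (!identical(sort(m$residue_index), sort(idx)))
      stop_invalid("epitope maps cover different residue index spaces")
  ord <- order(idx)
  cls <- vapply(maps, function(m)
    as.character(m$class[match(sort(idx), m$residue_index)]),
    character(length(idx)))
  highish <- cls %in% c("high", "disappeared-high")
  moderate_up <- cls %in% c("moderate", "high", "disappeared-high")
  dim(highish) <- dim(moderate_up) <- dim(cls)
  in_consensus <- apply(highish, 1, any) & apply(moderate_up, 1, all)
  labs <- vapply(seq_along(maps), function(i) {
    l <- attr(maps[[i]], "ligand_label")
    if (is.na(l) || !nzchar(l)) paste0("map", i) else l
  }, character(1))
  colnames(cls) <- make.unique(labs)
  out <- data.frame(residue_index = sort(idx),
                    residue_code = maps[[1]]$residue_code[ord])
  out <- cbind(out, as.data.frame(cls))
  out$in_consensus <- in_consensus
  out
}
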