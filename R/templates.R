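#' Landmark templates for lateral-view skull shapes
#'
#' Built-in template configurations used by the synthetic-data generator and
#' as the reference role structure for real digitized samples. `cranium19` is
#' a 19-point lateral-view cranium scheme (13 fixed landmarks, 6 sliding
#' semi-landmarks on the facial contour, the cranial vault and the orbit
#' margin); `mandible10` is a 10-point hemimandible scheme (4 fixed, 6 semis
#' on the ventral and posterior ramus contours).
#'
#' A template is a list with elements:
#' \describe{
#'   \item{points}{k x 2 matrix of template coordinates (arbitrary units).}
#'   \item{fixed_idx, semi_idx}{1-based index vectors, disjoint, covering 1..k.}
#'   \item{curves}{list of integer vectors, each an ordered chain of landmark
#'     indices along one curve; chain ends are fixed landmarks, interior
#'     points are semi-landmarks.}
#'   \item{region_partition}{named list of 1-based index vectors.}
#' }
#'
#' The cranium partition follows the usual face/braincase split: face =
#' {1-5, 11-13}, braincase = {6-10, 14-19}.
#'
#' @param name one of `"cranium19"`, `"mandible10"`.
#' @return a template list (class `"shape_template"`).
#' @export
#' @examples
#' tpl <- shape_template("cranium19")
#' nrow(tpl$points)
shape_template <- function(name = c("cranium19", "mandible10")) {
  name <- match.arg(name)
  if (name == "cranium19") {
    pts <- rbind(
      c(0.00, 0.45),  # 1  anterior tip of nasal
      c(0.02, 0.22),  # 2  prosthion
      c(0.40, 0.10),  # 3  anterior cheek-tooth alveolus
      c(0.85, 0.08),  # 4  posterior molar alveolus
      c(1.10, 0.20),  # 5  anterior zygomatic root
      c(1.45, 0.08),  # 6  glenoid fossa
      c(1.85, 0.10),  # 7  posterior zygomatic root
      c(2.10, 0.22),  # 8  auditory region
      c(2.25, 0.62),  # 9  posterodorsal occiput
      c(2.30, 0.35),  # 10 posterior occipital condyle
      c(0.92, 0.86),  # 11 posterior end of facial contour
      c(0.35, 0.66),  # 12 semi, facial contour
      c(0.65, 0.79),  # 13 semi, facial contour
      c(1.02, 0.74),  # 14 semi, orbit-to-vault
      c(1.08, 0.92),  # 15 anterior point of cranial vault
      c(1.42, 0.99),  # 16 semi, vault
      c(1.76, 0.96),  # 17 semi, vault
      c(2.06, 0.84),  # 18 semi, vault
      c(0.95, 0.55)   # 19 orbit, point of maximum curvature
    )
    out <- list(
      points = pts,
      fixed_idx = c(1:11, 15L, 19L),
      semi_idx = c(12L, 13L, 14L, 16L, 17L, 18L),
      curves = list(
        c(1L, 12L, 13L, 11L),          # facial dorsal contour
        c(15L, 16L, 17L, 18L, 9L),     # cranial vault
        c(19L, 14L, 15L)               # orbit to vault
      ),
      region_partition = list(
        face = c(1:5, 11:13),
        braincase = c(6:10, 14:19),
        cranium = 1:19
      )
    )
  } else {
    pts <- rbind(
      c(0.00, 0.28),  # 1 anterior alveolar tip
      c(0.12, 0.05),  # 2 anteroventral border
      c(1.90, 0.78),  # 3 tip of condyloid process
      c(1.95, 0.12),  # 4 angular process
      c(0.55, 0.00),  # 5 semi, ventral contour
      c(0.95, 0.00),  # 6 semi, ventral contour
      c(1.35, 0.02),  # 7 semi, ventral contour
      c(1.68, 0.06),  # 8 semi, ventral contour
      c(2.00, 0.55),  # 9 semi, posterior ramus
      c(2.02, 0.33)   # 10 semi, posterior ramus
    )
    out <- list(
      points = pts,
      fixed_idx = 1:4,
      semi_idx = 5:10,
      curves = list(
        c(2L, 5L, 6L, 7L, 8L, 4L),     # ventral contour
        c(3L, 9L, 10L, 4L)             # posterior ramus contour
      ),
      region_partition = list(mandible = 1:10)
    )
  }
  out$name <- name
  class(out) <- "shape_template"
  validate_template(out)
  out
}

validate_template <- function(tpl) {
  k <- nrow(tpl$points)
  idx <- sort(c(tpl$fixed_idx, tpl$semi_idx))
  if (!identical(as.integer(idx), seq_len(k)))
    stop("fixed_idx and semi_idx must partition 1..k")
  nb <- semi_neighbors(tpl$curves, tpl$semi_idx)
  for (s in as.character(tpl$semi_idx)) {
    if (is.null(nb[[s]]) || length(nb[[s]]) != 2L)
      stop("semi-landmark ", s, " must have exactly two curve neighbors")
  }
  invisible(tpl)
}

# neighbor pairs for each semi-landmark from ordered curve chains
semi_neighbors <- function(curves, semi_idx) {
  nb <- list()
  for (ch in curves) {
    if (length(ch) < 3L) next
    for (i in seq(2L, length(ch) - 1L)) {
      if (ch[i] %in% semi_idx)
        nb[[as.character(ch[i])]] <- c(ch[i - 1L], ch[i + 1L])
    }
  }
  nb
}

#' Restrict a template to a subset of landmarks
#'
#' Subsets `points`, role vectors and curves to the given 1-based indices and
#' renumbers everything to 1..length(indices). Semi-landmarks whose curve
#' neighbors are not both retained are demoted to fixed landmarks (with a
#' warning), since their sliding direction is undefined on the subset.
#'
#' @param tpl a `shape_template`.
#' @param indices 1-based landmark indices to keep (in the template's frame).
#' @return a `shape_template` for the subset.
#' @export
subset_template <- function(tpl, indices) {
  indices <- as.integer(indices)
  if (anyDuplicated(indices) || any(indices < 1L) || any(indices > nrow(tpl$points)))
    stop("invalid landmark indices for this template")
  remap <- integer(nrow(tpl$points))
  remap[indices] <- seq_along(indices)
  keep_curve <- function(ch) {
    runs <- split(ch, cumsum(!(ch %in% indices)))
    lapply(runs, function(r) r[r %in% indices])
  }
  new_curves <- list()
  for (ch in tpl$curves) {
    if (all(ch %in% indices)) {
      new_curves[[length(new_curves) + 1L]] <- remap[ch]
    }
  }
  semi_keep <- intersect(tpl$semi_idx, indices)
  # semis that lost their curve context become fixed
  nb <- semi_neighbors(tpl$curves, tpl$semi_idx)
  demoted <- integer(0)
  for (s in semi_keep) {
    n2 <- nb[[as.character(s)]]
    ok <- all(n2 %in% indices)
    # also require the whole chain containing s to be retained (curve kept)
    in_kept_curve <- any(vapply(tpl$curves, function(ch)
      (s %in% ch) && all(ch %in% indices), logical(1)))
    if (!ok || !in_kept_curve) demoted <- c(demoted, s)
  }
  if (length(demoted))
    warning("semi-landmarks ", paste(demoted, collapse = ", "),
            " demoted to fixed in subset (curve neighbors not retained)")
  semi_new <- setdiff(semi_keep, demoted)
  out <- list(
    points = tpl$points[indices, , drop = FALSE],
    fixed_idx = sort(remap[setdiff(indices, semi_new)]),
    semi_idx = sort(remap[semi_new]),
    curves = new_curves,
    region_partition = NULL,
    name = paste0(tpl$name, "_subset")
  )
  class(out) <- "shape_template"
  if (length(out$semi_idx)) validate_template(out)
  out
}
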