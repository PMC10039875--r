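#' Slice-reference anatomical coordinates from three orthogonal planes
#'
#' Standardizes cell positions across slices: a least-squares plane
#' through the recorded slice-surface points (signed distance = depth in
#' the slice, the AP position), a midline plane through the dorsal and
#' ventral midline ends orthogonalized to the surface plane (distance =
#' ML), and a dorsal-end plane orthogonal to both through the dorsal end
#' (distance = DV).
#'
#' @param surface_points matrix/data frame of >= 3 non-collinear points
#'   (x, y, z in um) on the slice surface.
#' @param midline_dorsal,midline_ventral the two midline end points.
#' @param cells matrix/data frame of cell positions (x, y, z in um).
#' @return Tibble with `ap_um`, `ml_um`, `dv_um` per cell (AP positive
#'   into the slice).
#' @export
slice_coordinate_transform <- function(surface_points, midline_dorsal,
                                       midline_ventral, cells) {
  sp <- as.matrix(surface_points)
  if (nrow(sp) < 3) abort("need at least 3 surface points")
  ctr <- colMeans(sp)
  sv <- svd(sweep(sp, 2, ctr))
  if (sv$d[2] < 1e-9 * sv$d[1]) abort("surface points are collinear")
  n_surf <- sv$v[, 3]

  d_md <- as.numeric(midline_dorsal)
  d_mv <- as.numeric(midline_ventral)
  axis_dv <- d_md - d_mv
  # midline-plane normal: orthogonal to the surface normal and to the
  # dorsoventral midline axis
  n_mid <- pracma_cross(n_surf, axis_dv)
  if (sqrt(sum(n_mid^2)) < 1e-12) {
    abort("midline axis is parallel to the surface normal")
  }
  n_mid <- n_mid / sqrt(sum(n_mid^2))
  n_dors <- pracma_cross(n_surf, n_mid)
  n_dors <- n_dors / sqrt(sum(n_dors^2))
  # orient: depth positive below the surface (opposite the outward normal
  # pointing toward the cells' mean), DV positive from dorsal toward ventral
  cm <- as.matrix(cells)
  if (sum((colMeans(cm) - ctr) * n_surf) > 0) n_surf <- -n_surf
  if (sum((d_mv - d_md) * n_dors) < 0) n_dors <- -n_dors

  signed <- function(x, p0, nv) drop(sweep(x, 2, p0) %*% nv)
  tibble::tibble(
    ap_um = -signed(cm, ctr, n_surf),
    ml_um = signed(cm, d_md, n_mid),
    dv_um = signed(cm, d_md, n_dors)
  )
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Map-level connectivity summaries
#'
#' Summarizes one connectivity map: the connection probability among
#' responsive cells within `radius_um` of the recorded cell, the mean
#' strength over connected cells (no radius cap), the weighted input
#' (mean strength over responsive cells counting non-connected cells as
#' zero), and directional weighted inputs split by the sign of the
#' presynaptic cell's ML and DV offset from the recorded cell.
#'
#' @param map tibble with one row per stimulated cell: `ml_um`, `dv_um`,
#'   (optional `ap_um`), `responsive` (logical), `connected` (logical),
#'   `strength_pa` (>= 0, 0 for non-connected).
#' @param recorded list/row with the recorded cell's `ml_um`, `dv_um`
#'   (and `ap_um` if present in `map`).
#' @param radius_um probability radius (default 300 um).
#' @return One-row tibble: `n_responsive`, `n_connected`,
#'   `probability`, `mean_strength_pa`, `weighted_input_pa`,
#'   `input_medial_pa`, `input_lateral_pa`, `input_dorsal_pa`,
#'   `input_ventral_pa`.
#' @export
map_summaries <- function(map, recorded, radius_um = 300) {
  stopifnot(all(c("ml_um", "dv_um", "responsive", "connected",
                  "strength_pa") %in% names(map)))
  if (any(map$connected & !map$responsive)) {
    abort("connected cells must be responsive")
  }
  if (any(map$strength_pa < 0)) abort("strengths must be >= 0")
  resp <- map[map$responsive, ]
  if (!nrow(resp)) abort("map has no responsive cells")
  dml <- resp$ml_um - recorded$ml_um
  ddv <- resp$dv_um - recorded$dv_um
  dap <- if ("ap_um" %in% names(resp) && !is.null(recorded$ap_um)) {
    resp$ap_um - recorded$ap_um
  } else 0
  dist <- sqrt(dml^2 + ddv^2 + dap^2)
  in_r <- dist <= radius_um
  prob <- if (any(in_r)) mean(resp$connected[in_r]) else NA_real_
  conn <- resp[resp$connected, ]
  dir_input <- function(sel) {
    if (!any(sel)) 0 else mean(resp$strength_pa[sel])
  }
  tibble::tibble(
    n_responsive = nrow(resp),
    n_connected = nrow(conn),
    probability = prob,
    mean_strength_pa = if (nrow(conn)) mean(conn$strength_pa) else NA_real_,
    weighted_input_pa = mean(resp$strength_pa),
    input_medial_pa = dir_input(dml < 0),
    input_lateral_pa = dir_input(dml > 0),
    input_dorsal_pa = dir_input(ddv < 0),
    input_ventral_pa = dir_input(ddv > 0)
  )
}

#' Co-stimulation bias from the spatial specificity of stimulation
#'
#' Counts, for every labeled cell, the neighbors inside its stimulation
#' ellipsoid (extents set by the full-width-at-half-maximum of the spiking
#' probability along the optical axis and radially). If a fraction
#' \eqn{f_{co}} of cells has at least one in-ellipsoid neighbor, the
#' measured connection probability overestimates truth by the factor
#' \eqn{1 + f_{co}}, i.e. a bias of \eqn{1 - 1/(1 + f_{co})}.
#'
#' @param positions tibble/matrix of cell positions (`x_um`, `y_um`,
#'   `z_um`; z is the optical axis).
#' @param fwhm_axial_um,fwhm_radial_um FWHM of spiking probability along
#'   and across the optical axis (defaults 55.9 and 24.2 um).
#' @param semantics `"full_axis"` (default: ellipsoid full axis = FWHM,
#'   semi-axis FWHM/2) or `"semi_axis"` (semi-axis = FWHM).
#' @return A list of class `costim_bias`: `f_co` (fraction of cells with
#'   >= 1 neighbor), `mean_neighbors` (among those), `pair_fraction`
#'   (in-ellipsoid fraction of all pairs), `bias` (in [0, 0.5)).
#' @export
costimulation_bias <- function(positions, fwhm_axial_um = 55.9,
                               fwhm_radial_um = 24.2,
                               semantics = c("full_axis", "semi_axis")) {
  semantics <- match.arg(semantics)
  pos <- as.matrix(as.data.frame(positions)[, c("x_um", "y_um", "z_um")])
  n <- nrow(pos)
  if (n < 2) abort("need at least 2 cells")
  div <- if (semantics == "full_axis") 2 else 1
  ax <- fwhm_axial_um / div
  rad <- fwhm_radial_um / div
  scaled <- sweep(pos, 2, c(rad, rad, ax), "/")
  dd <- as.matrix(stats::dist(scaled))
  diag(dd) <- Inf
  neigh <- rowSums(dd <= 1)
  f_co <- mean(neigh >= 1)
  structure(list(
    f_co = f_co,
    mean_neighbors = if (any(neigh >= 1)) mean(neigh[neigh >= 1]) else NA_real_,
    pair_fraction = sum(dd <= 1) / (n * (n - 1)),
    bias = costim_bias_from_fraction(f_co)
  ), class = "costim_bias")
}

#' Connection-probability bias implied by a co-stimulation fraction
#'
#' @param f_co fraction of cells with at least one in-ellipsoid neighbor.
#' @return Bias fraction `1 - 1/(1 + f_co)`.
#' @examples
#' costim_bias_from_fraction(0.13)  # ~0.115
#' @export
costim_bias_from_fraction <- function(f_co) {
  assert_positive(f_co, "f_co", strict = FALSE)
  1 - 1 / (1 + f_co)
}

#' Connectivity above vs. below the recorded cell's depth
#'
#' Compares connectivity between two equal-thickness shells of each map:
#' presynaptic cells between the slice surface and the recorded cell's
#' depth ("above") versus those between that depth and twice it
#' ("below"). Equal volumes differing only in distance from the cut
#' surface, so their ratio measures the connection loss from slicing.
#'
#' @param maps tibble with one row per stimulated cell across maps:
#'   `map_id`, `depth_um` (cell depth in slice), `recorded_depth_um`,
#'   `responsive`, `connected`, `strength_pa`.
#' @return One-row tibble: probabilities and mean strengths per shell and
#'   the below/above probability ratio.
#' @export
depth_split_connectivity <- function(maps) {
  m <- dplyr::mutate(tibble::as_tibble(maps),
    shell = dplyr::case_when(
      .data$depth_um <= .data$recorded_depth_um ~ "above",
      .data$depth_um <= 2 * .data$recorded_depth_um ~ "below",
      TRUE ~ NA_character_
    ))
  m <- m[!is.na(m$shell) & m$responsive, ]
  agg <- dplyr::summarise(
    dplyr::group_by(m, .data$shell),
    probability = mean(.data$connected),
    mean_strength_pa = ifelse(any(.data$connected),
                              mean(.data$strength_pa[.data$connected]),
                              NA_real_),
    n = dplyr::n(), .groups = "drop")
  get <- function(sh, col) {
    x <- agg[[col]][agg$shell == sh]
    if (length(x)) x else NA_real_
  }
  tibble::tibble(
    prob_above = get("above", "probability"),
    prob_below = get("below", "probability"),
    strength_above_pa = get("above", "mean_strength_pa"),
    strength_below_pa = get("below", "mean_strength_pa"),
    n_above = get("above", "n"), n_below = get("below", "n"),
    ratio_below_above = get("below", "probability") /
      get("above", "probability")
  )
}

#' Light-power multiplier compensating tissue attenuation
#'
#' Two-photon excitation decays approximately monoexponentially with
#' imaging depth; holding focal-point power constant therefore requires
#' scaling the delivered power by \eqn{e^{depth/\tau}}.
#'
#' @param depth_um focal depth in tissue (um, >= 0).
#' @param tau_um attenuation length (default 147.6 um).
#' @return Power multiplier (>= 1).
#' @examples
#' attenuation_compensation(147.6)  # e
#' @export
attenuation_compensation <- function(depth_um, tau_um = 147.6) {
  assert_positive(depth_um, "depth_um", strict = FALSE)
  assert_positive(tau_um, "tau_um")
  exp(depth_um / tau_um)
}
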