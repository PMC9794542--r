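#' Synthetic-data configuration
#'
#' Controls the generators that stand in for the physical crimp-bench
#' measurements and the CT stent segmentations.
#'
#' @param seed integer RNG seed; equal configurations give byte-equal
#'   output
#' @param noise_sd_rel multiplicative force-noise standard deviation
#' @param perturbation_sd isotropic geometric noise (mm) for
#'   pseudo-segmentations
#' @param n_samples samples per strut polyline in pseudo-segmentations
#' @return object of class `synth_config`
#' @export
synth_config <- function(seed = 1L, noise_sd_rel = 0.01,
                         perturbation_sd = 0.1, n_samples = 200L) {
  stopifnot(noise_sd_rel >= 0, perturbation_sd >= 0)
  structure(list(seed = as.integer(seed), noise_sd_rel = noise_sd_rel,
                 perturbation_sd = perturbation_sd,
                 n_samples = as.integer(n_samples)),
            class = "synth_config")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic experimental crimp curve
#'
#' Runs the ring model at the given parameters and adds multiplicative
#' Gaussian noise, emulating a bench radial-force measurement.
#'
#' @param params [nitinol_params()]
#' @param spec [ring_spec()]
#' @param proto [crimp_protocol()]
#' @param synth [synth_config()]
#' @param ring_model model function, surrogate by default
#' @return `force_diameter_curve` data.frame
#' @export
gen_synthetic_curve <- function(params, spec, proto, synth = synth_config(),
                                ring_model = ring_crimp_surrogate) {
  curve <- ring_model(spec, params, proto)
  if (synth$noise_sd_rel > 0) {
    curve$force <- with_seed(synth$seed,
      curve$force * (1 + rnorm(nrow(curve), 0, synth$noise_sd_rel)))
    curve$force[curve$force < 0] <- 0
  }
  curve
}

#' Pseudo-segmentation of a deployed device
#'
#' Perturbs the stent strut polylines and ring apex sets of a deployed
#' state with seeded isotropic Gaussian noise, standing in for a CT
#' segmentation of the stent (synthetic; no imaging involved).
#'
#' @param devstate a deployed `device_state` (see [apply_prestress()] /
#'   [run_deployment()]) or a plain list with `x` (coordinates) and
#'   `beam` (beam_mesh)
#' @param synth [synth_config()]
#' @return list with per-ring elements: `polyline` (perturbed strut
#'   nodes, ordered along the wire), `apexes` (perturbed proximal apex
#'   points), `ring_id`
#' @export
gen_pseudo_segmentation <- function(devstate, synth = synth_config()) {
  beam <- devstate$beam
  x <- devstate$x
  with_seed(synth$seed, {
    lapply(seq_along(beam$rings), function(k) {
      idx <- beam$rings[[k]]$nodes
      pts <- x[idx, , drop = FALSE]
      noise <- matrix(rnorm(length(pts), 0, synth$perturbation_sd),
                      nrow(pts), 3)
      poly <- pts + noise
      ap_idx <- beam$rings[[k]]$apex_prox
      apexes <- if (length(ap_idx)) {
        poly[match(ap_idx, idx), , drop = FALSE]
      } else {
        # thin ring: uniform subsample of the circle
        poly[round(seq(1, nrow(poly), length.out = 17))[-17], , drop = FALSE]
      }
      list(ring_id = k, polyline = poly, apexes = apexes)
    })
  })
}
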