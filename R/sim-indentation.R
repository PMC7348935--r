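#' Indentation curve container
#'
#' Builds the tabular record of one spherical indentation: piezo displacement
#' `z_um` (micrometres, monotone non-decreasing during loading) and measured
#' load `load_uN` (micronewtons), with probe metadata (tip radius, cantilever
#' stiffness, Poisson ratio) carried as attributes. All downstream analysis
#' converts to SI internally, so the stored instrument units are free.
#'
#' @param z_um Piezo displacement samples in micrometres.
#' @param load_uN Load samples in micronewtons (same length as `z_um`).
#' @param tip_radius_um Spherical tip radius in micrometres (> 0).
#' @param stiffness_N_per_m Cantilever stiffness in newtons per metre (> 0).
#' @param poisson_ratio Poisson ratio of the sample, in `[0, 0.5]`.
#'
#' @return A tibble of class `indentation_curve` with columns `z_um`,
#'   `load_uN`.
#' @export
indentation_curve <- function(z_um, load_uN,
                              tip_radius_um = 53.5,
                              stiffness_N_per_m = 4.53,
                              poisson_ratio = 0.5) {
  if (length(z_um) != length(load_uN) || length(z_um) < 10L) {
    abort("`z_um` and `load_uN` must have equal length >= 10 samples.")
  }
  if (is.unsorted(z_um)) abort("`z_um` must be monotone non-decreasing.")
  if (tip_radius_um <= 0) abort("`tip_radius_um` must be > 0.")
  if (stiffness_N_per_m <= 0) abort("`stiffness_N_per_m` must be > 0.")
  if (poisson_ratio < 0 || poisson_ratio > 0.5) {
    abort("`poisson_ratio` must lie in [0, 0.5].")
  }
  out <- tibble(z_um = as.numeric(z_um), load_uN = as.numeric(load_uN))
  attr(out, "tip_radius_um") <- tip_radius_um
  attr(out, "stiffness_N_per_m") <- stiffness_N_per_m
  attr(out, "poisson_ratio") <- poisson_ratio
  class(out) <- c("indentation_curve", class(out))
  out
}

#' Simulate a spherical nano-indentation load-displacement curve
#'
#' Generates the displacement-controlled record of a spherical probe indenting
#' a linear-elastic half-space. Post-contact, the load on true depth `h`
#' follows the Hertz relation
#' `P = (4/3) * (E / (1 - nu^2)) * sqrt(R) * h^(3/2)`,
#' and the piezo travel is `z = contact_offset + h + P / k`: the cantilever
#' (stiffness `k`) deflects by `P / k`, so piezo travel exceeds sample
#' indentation. A pre-contact baseline of `contact_offset` micrometres of
#' zero-load travel precedes contact. Optional Gaussian load noise (a
#' fraction of the maximum load) is added to every sample.
#'
#' Defaults mirror a soft-tissue indentation protocol: 53.5 um tip radius,
#' 4.53 N/m cantilever, ~10 um indentation depth, incompressible sample
#' (`nu = 0.5`).
#'
#' @param true_modulus_Pa Ground-truth elastic modulus E in pascals (> 0).
#' @param poisson_ratio Poisson ratio in `[0, 0.5]`.
#' @param tip_radius_um Tip radius R in micrometres.
#' @param max_depth_um Maximum true indentation depth in micrometres (> 0).
#' @param stiffness_N_per_m Cantilever stiffness k in N/m.
#' @param load_noise_sd Gaussian load noise SD as a fraction of max load.
#' @param contact_offset_um Pre-contact piezo travel in micrometres (>= 0).
#' @param n_pre,n_post Number of pre- and post-contact samples.
#' @param seed Integer seed.
#'
#' @return An [indentation_curve()] whose `ground_truth` attribute records the
#'   generator parameters and the exact per-sample true depth `h_um`.
#' @export
#'
#' @examples
#' crv <- sim_indentation_curve(1000, seed = 1)
#' elastic_modulus(crv)$E_Pa
sim_indentation_curve <- function(true_modulus_Pa,
                                  poisson_ratio = 0.5,
                                  tip_radius_um = 53.5,
                                  max_depth_um = 10,
                                  stiffness_N_per_m = 4.53,
                                  load_noise_sd = 0,
                                  contact_offset_um = 2,
                                  n_pre = 50L,
                                  n_post = 200L,
                                  seed = 1L) {
  if (true_modulus_Pa <= 0) abort("`true_modulus_Pa` must be > 0.")
  if (max_depth_um <= 0) abort("`max_depth_um` must be > 0.")
  if (contact_offset_um < 0) abort("`contact_offset_um` must be >= 0.")
  if (poisson_ratio < 0 || poisson_ratio > 0.5) {
    abort("`poisson_ratio` must lie in [0, 0.5].")
  }

  withr_seed(seed, {
    R_m <- tip_radius_um * 1e-6
    h_m <- seq(0, max_depth_um * 1e-6, length.out = n_post + 1L)[-1L]
    P_N <- hertz_load(h_m, true_modulus_Pa, poisson_ratio, R_m)
    z_post_m <- contact_offset_um * 1e-6 + h_m + P_N / stiffness_N_per_m

    z_pre_m <- if (n_pre > 0 && contact_offset_um > 0) {
      seq(0, contact_offset_um * 1e-6, length.out = n_pre + 1L)[-(n_pre + 1L)]
    } else {
      numeric(0)
    }
    z_m <- c(z_pre_m, z_post_m)
    P_all <- c(rep(0, length(z_pre_m)), P_N)
    if (load_noise_sd > 0) {
      P_all <- P_all + rnorm(length(P_all), 0, load_noise_sd * max(P_N))
    }

    crv <- indentation_curve(
      z_um = z_m * 1e6,
      load_uN = P_all * 1e6,
      tip_radius_um = tip_radius_um,
      stiffness_N_per_m = stiffness_N_per_m,
      poisson_ratio = poisson_ratio
    )
    attr(crv, "ground_truth") <- list(
      true_modulus_Pa = true_modulus_Pa,
      poisson_ratio = poisson_ratio,
      tip_radius_um = tip_radius_um,
      max_depth_um = max_depth_um,
      stiffness_N_per_m = stiffness_N_per_m,
      contact_offset_um = contact_offset_um,
      h_um = h_m * 1e6,
      seed = seed
    )
    crv
  })
}

# Hertz load for a sphere of radius R_m on an elastic half-space, SI units.
hertz_load <- function(h_m, E_Pa, nu, R_m) {
  (4 / 3) * (E_Pa / (1 - nu^2)) * sqrt(R_m) * h_m^1.5
}
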