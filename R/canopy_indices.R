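#' A 16-sector surface-temperature profile
#'
#' @param values 16 canopy-wall surface temperatures, degrees C, base to
#'   top. Values outside the plausible -20 to 70 degrees C range trigger a
#'   warning, not an error.
#' @return An object of class `thermal_profile`.
#' @export
thermal_profile <- function(values) {
  values <- as.numeric(values)
  if (length(values) != 16L) stop("an ST profile has exactly 16 sectors",
                                  call. = FALSE)
  if (anyNA(values)) stop("ST values must not be missing", call. = FALSE)
  if (any(values < -20 | values > 70)) {
    warning("surface temperatures outside the plausible -20 to 70 C range")
  }
  structure(list(values = values), class = "thermal_profile")
}

#' Background (sky) temperature model
#'
#' The thermal sensor reading mixes vegetation and sky background; the
#' background contribution sits a few degrees C above zero. The default is a
#' fixed 4 degrees C; [estimate_background()] derives it from the
#' below-canopy ST sectors instead.
#'
#' @param t_background Background temperature, degrees C.
#' @param source `"fixed"` or `"estimated-from-sky-sectors"`.
#' @param vegetation_bound Sanity bound: `t_background` must stay below this
#'   typical vegetation temperature (default 20 degrees C).
#' @return An object of class `background_model`.
#' @export
background_model <- function(t_background = 4, source = "fixed",
                             vegetation_bound = 20) {
  stop_if_not_scalar_number(t_background, "t_background")
  if (t_background >= vegetation_bound) {
    stop("t_background must be below the vegetation temperature bound (",
         vegetation_bound, " C)", call. = FALSE)
  }
  structure(list(t_background = t_background, source = source),
            class = "background_model")
}

#' @describeIn background_model Estimate the background temperature as the
#'   mean of ST sectors 1-5 (below the CI range, sky/ground dominated).
#' @param st A [thermal_profile()].
#' @export
estimate_background <- function(st, vegetation_bound = 20) {
  stopifnot(inherits(st, "thermal_profile"))
  background_model(mean(st$values[1:5]), source = "estimated-from-sky-sectors",
                   vegetation_bound = vegetation_bound)
}

#' Center of gravity of the vertical vegetation distribution
#'
#' CI-weighted mean sector index, `COG = sum(s * CI_s) / sum(CI_s)` over
#' sectors `s = 1..15`: the CI sector where the center of gravity of the
#' vegetation distribution is located.
#'
#' @param profile A [sector_profile()] (or a plain vector of 15 CI values).
#' @return Real number in `[1, 15]`.
#' @export
center_of_gravity <- function(profile) {
  ci <- profile_values15(profile)
  total <- sum(ci)
  if (total <= 0) stop("all-zero profile: center of gravity undefined",
                       call. = FALSE)
  sum(seq_len(15L) * ci) / total
}

#' Moment of inertia of the vegetation distribution
#'
#' `MOI = sum(CI_s * (s - COG)^2)`: the more the vegetation is dispersed
#' around its center of gravity, the higher the MOI.
#'
#' @inheritParams center_of_gravity
#' @return Non-negative real number.
#' @export
moment_of_inertia <- function(profile) {
  ci <- profile_values15(profile)
  cog <- center_of_gravity(profile)
  sum(ci * (seq_len(15L) - cog)^2)
}

profile_values15 <- function(profile) {
  ci <- if (inherits(profile, "sector_profile")) profile$values else
    as.numeric(profile)
  if (length(ci) != 15L || anyNA(ci)) {
    stop("need 15 non-missing CI sector values", call. = FALSE)
  }
  if (any(ci < 0)) stop("CI values must be non-negative", call. = FALSE)
  ci
}

#' Background-corrected canopy surface temperature per macro-sector
#'
#' A thermal sector reading is the mixture
#' `ST = T_V * F_V + T_B * (1 - F_V)` of the vegetation temperature `T_V`
#' and the sky background `T_B`, weighted by the vegetated fraction `F_V`.
#' With CI as a direct gap quantification (`F_V = mean CI / 1000`), the
#' default `"inversion"` mode solves the mixture for the unbiased vegetation
#' temperature per macro-sector:
#' `T_V = (mean ST - T_B * (1 - F_V)) / F_V`. The alternative `"ratio"` mode
#' returns the plain `mean ST / mean CI` ratio.
#'
#' @param st A [thermal_profile()] (16 sectors).
#' @param ci A [sector_profile()] (15 sectors).
#' @param bg A [background_model()]; default fixed 4 degrees C.
#' @param mode `"inversion"` (default) or `"ratio"`.
#' @param macro_map Macro-sector definition, default [macro_sector_map()].
#' @return A data frame of class `normalized_st` with one row per
#'   macro-sector: `macro`, `st_mean`, `f_v`, `f_b` and `value` (`T_V` in
#'   inversion mode, the ST/CI ratio otherwise). Bare-sky macro-sectors
#'   (`F_V = 0`, or mean CI = 0 in ratio mode) are flagged missing (`NA`).
#' @export
ci_normalized_st <- function(st, ci, bg = background_model(),
                             mode = c("inversion", "ratio"),
                             macro_map = macro_sector_map()) {
  stopifnot(inherits(st, "thermal_profile"), inherits(ci, "sector_profile"),
            inherits(bg, "background_model"))
  mode <- match.arg(mode)
  if (anyNA(ci$values)) stop("CI profile has missing sectors", call. = FALSE)
  rows <- lapply(names(macro_map), function(nm) {
    ms <- macro_map[[nm]]
    st_mean <- mean(st$values[ms$st])
    ci_mean <- mean(ci$values[ms$ci])
    f_v <- ci_mean / 1000
    value <- if (mode == "inversion") {
      if (f_v <= 0) NA_real_ else
        (st_mean - bg$t_background * (1 - f_v)) / f_v
    } else {
      if (ci_mean <= 0) NA_real_ else st_mean / ci_mean
    }
    data.frame(macro = nm, st_mean = st_mean, f_v = f_v, f_b = 1 - f_v,
               value = value)
  })
  out <- do.call(rbind, rows)
  attr(out, "mode") <- mode
  attr(out, "t_background") <- bg$t_background
  class(out) <- c("normalized_st", "data.frame")
  out
}

#' Forward thermal mixture
#'
#' Composes the mixture `ST = T_V * F_V + T_B * (1 - F_V)`; mainly useful to
#' verify that [ci_normalized_st()] inverts it exactly.
#'
#' @param t_v Vegetation temperature, degrees C.
#' @param t_b Background temperature, degrees C.
#' @param f_v Vegetated fraction in `[0, 1]`.
#' @return The mixed surface-temperature reading.
#' @export
st_mixture <- function(t_v, t_b, f_v) {
  if (any(f_v < 0 | f_v > 1)) stop("f_v must lie in [0, 1]", call. = FALSE)
  t_v * f_v + t_b * (1 - f_v)
}
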