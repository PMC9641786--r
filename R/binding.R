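# Mass-action binding equilibrium of thyroxine among its carrier proteins.
#
# T4 distributes between a free pool and three 1:1 carriers (TBG,
# transthyretin, albumin).  At equilibrium, with association constant Ka_i
# (L/nmol) and total carrier concentration P_i (nmol/L),
#
#   bound_i = P_i * Ka_i * F / (1 + Ka_i * F),
#   total   = F + sum_i bound_i,
#
# where F is the free T4 concentration (nmol/L).  All public concentrations
# use the field's customary units: free fT4 in pmol/L, total T4 and TBG in
# nmol/L, transthyretin (TTR) in umol/L, albumin in g/L.

#' Molar mass used to convert albumin g/L to nmol/L
#'
#' Human serum albumin, 66,500 g/mol.
#' @keywords internal
ALBUMIN_MW_G_PER_MOL <- 66500

#' Convert an albumin mass concentration to a molar concentration
#'
#' @param albumin_gl Albumin concentration in g/L.
#' @return Albumin concentration in nmol/L (mass / 66,500 g/mol).
#' @export
#' @examples
#' albumin_gl_to_nmol(41.8)
albumin_gl_to_nmol <- function(albumin_gl) {
  albumin_gl / ALBUMIN_MW_G_PER_MOL * 1e9
}

#' Association constants of the three T4 carrier proteins
#'
#' Bundles the mass-action association constants (L/nmol) of
#' thyroxine-binding globulin (TBG), transthyretin (TTR) and albumin.
#' Affinities must respect the physiological ordering TBG > TTR > albumin.
#'
#' @param ka_tbg,ka_ttr,ka_alb Association constants in L/nmol, all
#'   strictly positive, with `ka_tbg > ka_ttr > ka_alb`.
#' @return An object of class `binding_constants`.
#' @seealso [calibrate_binding_constants()] to derive constants from a
#'   bound-fraction specification.
#' @export
binding_constants <- function(ka_tbg, ka_ttr, ka_alb) {
  ka <- c(tbg = ka_tbg, ttr = ka_ttr, alb = ka_alb)
  if (!all(is.finite(ka)) || any(ka <= 0)) {
    stop("all association constants must be finite and strictly positive")
  }
  if (!(ka_tbg > ka_ttr && ka_ttr > ka_alb)) {
    stop("affinity ordering violated: require ka_tbg > ka_ttr > ka_alb")
  }
  structure(list(ka_tbg = ka_tbg, ka_ttr = ka_ttr, ka_alb = ka_alb),
            class = "binding_constants")
}

#' @export
print.binding_constants <- function(x, ...) {
  cat("T4 carrier association constants (L/nmol):\n")
  cat(sprintf("  TBG: %.6g  TTR: %.6g  albumin: %.6g\n",
              x$ka_tbg, x$ka_ttr, x$ka_alb))
  invisible(x)
}

#' Reference serum composition used to calibrate binding constants
#'
#' The healthy-control binder profile: TBG 302 nmol/L, TTR 4.6 umol/L,
#' albumin 41.8 g/L, with a nominal total T4 of 100 nmol/L.
#'
#' @param total_t4 Total T4, nmol/L.
#' @param tbg TBG, nmol/L.
#' @param ttr Transthyretin, umol/L.
#' @param albumin_gl Albumin, g/L.
#' @return A list with the four components, class `reference_serum`.
#' @export
reference_serum <- function(total_t4 = 100, tbg = 302, ttr = 4.6,
                            albumin_gl = 41.8) {
  if (any(c(total_t4, tbg, ttr, albumin_gl) <= 0)) {
    stop("reference serum concentrations must be strictly positive")
  }
  structure(list(total_t4 = total_t4, tbg = tbg, ttr = ttr,
                 albumin_gl = albumin_gl),
            class = "reference_serum")
}

# Carrier totals in nmol/L, in the canonical (tbg, ttr, alb) order.
binder_totals_nmol <- function(tbg, ttr, albumin_gl) {
  c(tbg = tbg, ttr = ttr * 1000, alb = albumin_gl_to_nmol(albumin_gl))
}

#' Calibrate carrier association constants from a bound-fraction spec
#'
#' Inverts the mass-action equilibrium at a reference serum composition so
#' that the carriers hold prescribed shares of total T4.  The canonical
#' partition has 75% of T4 on TBG, 10% on transthyretin and 12% on albumin
#' with a free fraction of 0.02%; because those shares do not sum to 100%,
#' the bound shares are renormalized to `1 - f_free` while preserving their
#' 75:10:12 ratios, which keeps the free fraction exact.
#'
#' For carrier i holding `bound_i = share_i * total` with free
#' `F = f_free * total`, the association constant is
#' `Ka_i = bound_i / (F * (P_i - bound_i))`.
#'
#' @param reference A [reference_serum()] giving carrier totals and total T4.
#' @param f_free Free fraction of total T4 at the reference composition
#'   (default 2e-4, i.e. 0.02%).
#' @param bound_ratios Relative bound shares for (TBG, TTR, albumin);
#'   renormalized to sum to `1 - f_free`.
#' @return A [binding_constants()] object.  Forward-solving with it at the
#'   reference composition reproduces `f_free` to within 1e-9 relative.
#' @export
#' @examples
#' ka <- calibrate_binding_constants()
#' eq <- solve_free_t4(100, tbg = 302, ttr = 4.6, albumin_gl = 41.8,
#'                     constants = ka)
#' eq$free_pmol / 1000 / 100  # 2e-4
calibrate_binding_constants <- function(reference = reference_serum(),
                                        f_free = 2e-4,
                                        bound_ratios = c(tbg = 75, ttr = 10,
                                                         alb = 12)) {
  stopifnot(inherits(reference, "reference_serum"))
  if (f_free <= 0 || f_free >= 1) stop("f_free must lie in (0, 1)")
  if (length(bound_ratios) != 3L || any(bound_ratios <= 0)) {
    stop("bound_ratios must be three positive shares (tbg, ttr, alb)")
  }
  total <- reference$total_t4
  shares <- bound_ratios / sum(bound_ratios) * (1 - f_free)
  bound <- shares * total
  free <- f_free * total
  p_tot <- binder_totals_nmol(reference$tbg, reference$ttr,
                              reference$albumin_gl)
  p_free <- p_tot - bound
  if (any(p_free <= 0)) {
    stop("infeasible calibration: a carrier would be saturated ",
         "(bound share exceeds its total concentration)")
  }
  ka <- bound / (free * p_free)
  binding_constants(ka[["tbg"]], ka[["ttr"]], ka[["alb"]])
}

# Equilibrium residual total - F - sum(bound_i(F)) and its derivative,
# both monotone in F, used by the root finder below.
equilibrium_residual <- function(free_nmol, total_t4, p_tot, ka) {
  total_t4 - free_nmol - sum(p_tot * ka * free_nmol / (1 + ka * free_nmol))
}

#' Solve the binding equilibrium for free T4 given total T4
#'
#' Finds the free T4 concentration `F` satisfying
#' `total = F + sum_i P_i * Ka_i * F / (1 + Ka_i * F)` by bracketed root
#' finding on `[0, total]` followed by Newton polishing.  The left side is
#' strictly decreasing in `F`, so the root is unique.
#'
#' @param total_t4 Total T4, nmol/L, strictly positive.
#' @param tbg TBG, nmol/L.
#' @param ttr Transthyretin, umol/L.
#' @param albumin_gl Albumin, g/L.
#' @param constants A [binding_constants()] object.
#' @return A list with `free_pmol` (free T4, pmol/L), `bound_tbg`,
#'   `bound_ttr`, `bound_alb` (nmol/L), `free_fraction` and the relative
#'   mass-balance `residual` (guaranteed <= 1e-9).
#' @export
solve_free_t4 <- function(total_t4, tbg, ttr, albumin_gl, constants) {
  stopifnot(inherits(constants, "binding_constants"))
  if (any(c(total_t4, tbg, ttr, albumin_gl) <= 0)) {
    stop("total T4 and carrier concentrations must be strictly positive")
  }
  p_tot <- binder_totals_nmol(tbg, ttr, albumin_gl)
  ka <- c(constants$ka_tbg, constants$ka_ttr, constants$ka_alb)

  f <- function(x) equilibrium_residual(x, total_t4, p_tot, ka)
  # f(0) = total > 0, f(total) = -sum(bound) <= 0; uniroot needs a sign
  # change, which only fails in the no-binding limit where F = total.
  if (f(total_t4) >= 0) {
    free <- total_t4
  } else {
    free <- stats::uniroot(f, c(0, total_t4), tol = 1e-12 * total_t4)$root
  }
  # Newton polish to push the relative residual well below 1e-9.
  for (i in 1:50) {
    r <- f(free)
    if (abs(r) <= 1e-12 * total_t4) break
    dr <- -1 - sum(p_tot * ka / (1 + ka * free)^2)
    free <- free - r / dr
  }
  bound <- p_tot * ka * free / (1 + ka * free)
  list(free_pmol = free * 1000,
       bound_tbg = bound[["tbg"]],
       bound_ttr = bound[["ttr"]],
       bound_alb = bound[["alb"]],
       free_fraction = free / total_t4,
       residual = abs(total_t4 - free - sum(bound)) / total_t4)
}

#' Total T4 implied by a free T4 concentration (closed form)
#'
#' The forward map from free to total is explicit:
#' `total = F + sum_i P_i * Ka_i * F / (1 + Ka_i * F)`.  This is the exact
#' inverse of [solve_free_t4()]; round-tripping recovers the free value to
#' 1e-9 relative.
#'
#' @param free_pmol Free T4, pmol/L (vectorized); zero maps to zero.
#' @inheritParams solve_free_t4
#' @return Total T4 in nmol/L, same length as `free_pmol`.
#' @export
invert_total_from_free <- function(free_pmol, tbg, ttr, albumin_gl,
                                   constants) {
  stopifnot(inherits(constants, "binding_constants"))
  if (any(free_pmol < 0)) stop("free T4 must be non-negative")
  if (any(c(tbg, ttr, albumin_gl) <= 0)) {
    stop("carrier concentrations must be strictly positive")
  }
  p_tot <- binder_totals_nmol(tbg, ttr, albumin_gl)
  ka <- c(constants$ka_tbg, constants$ka_ttr, constants$ka_alb)
  vapply(free_pmol / 1000, function(fr) {
    fr + sum(p_tot * ka * fr / (1 + ka * fr))
  }, numeric(1))
}
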