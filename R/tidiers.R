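#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.c4_aci_fit <- function(x, ...) {
  tibble(term = c("vpmax", "vcmax"),
         estimate = c(x$vpmax, x$vcmax),
         std.error = c(x$se_vpmax, x$se_vcmax))
}

#' @exportS3Method generics::glance
glance.c4_aci_fit <- function(x, ...) {
  tibble(rss = x$rss, n = x$n)
}

#' @exportS3Method generics::tidy
tidy.c4_bb_fit <- function(x, ...) {
  tibble(term = c("slope_bb", "intercept_bb"),
         estimate = c(x$slope_bb, x$intercept_bb),
         std.error = c(x$se_slope, x$se_intercept))
}

#' @exportS3Method generics::glance
glance.c4_bb_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, n = x$n)
}

#' @exportS3Method generics::tidy
tidy.c4_gs_fit <- function(x, ...) {
  tibble(term = c("g_max", "g_0", "k"),
         estimate = c(x$g_max, x$g_0, x$k))
}

#' @exportS3Method generics::glance
glance.c4_gs_fit <- function(x, ...) {
  tibble(rss = x$rss, n = x$n, direction = x$direction)
}

#' @exportS3Method generics::tidy
tidy.c4_tau_fit <- function(x, ...) {
  tibble(term = "tau_rubisco", estimate = x$tau_min)
}

#' @exportS3Method generics::glance
glance.c4_tau_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, n = x$n_used, a_final = x$a_final)
}

#' @exportS3Method generics::tidy
tidy.c4_pdrp_fit <- function(x, ...) {
  tibble(term = "pdrp", estimate = x$pdrp)
}

#' @exportS3Method generics::glance
glance.c4_induction_metrics <- function(x, ...) {
  tibble(it50_s = x$it50_s, mean_a_reduction_pct = x$mean_a_reduction_pct,
         min_ci = x$min_ci, a_steady = x$a_steady)
}
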