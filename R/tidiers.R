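#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a box-model run into its daily trajectory
#'
#' @param x A `box_run` from [run_box_model()].
#' @param ... Unused.
#' @return A tibble with one row per day: `day`, `sst`, `sss`, `ta`,
#'   `dic`, `pco2`, `flux`, `cum_uptake`.
#' @export
tidy.box_run <- function(x, ...) {
  x$trajectory
}

#' One-row summary of a box-model run
#'
#' @param x A `box_run`.
#' @param ... Unused.
#' @return A one-row tibble: region, C:N ratio, run window, initial and
#'   final DIC and pCO2, cumulative uptake, and the DIC budget closure
#'   residual (final minus initial DIC minus the summed step terms,
#'   umol kg-1; zero up to round-off).
#' @export
glance.box_run <- function(x, ...) {
  tr <- x$trajectory
  terms <- x$terms
  closure <- (dplyr::last(tr$dic) - tr$dic[1]) -
    sum(terms$d_flux + terms$d_ncp + terms$d_dil + terms$d_caco3)
  tibble::tibble(
    region = x$scenario$region, cn_ratio = x$scenario$cn_ratio,
    t_start = x$scenario$t_start, t_end = x$scenario$t_end,
    dic_initial = tr$dic[1], dic_final = dplyr::last(tr$dic),
    pco2_initial = tr$pco2[1], pco2_final = dplyr::last(tr$pco2),
    cum_uptake = dplyr::last(tr$cum_uptake),
    budget_residual = closure
  )
}
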