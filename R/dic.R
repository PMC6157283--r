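# DIC model selection: compare the animal model against the
# fixed-effects-only null and call nonzero heritability when the DIC
# improvement exceeds a threshold (default 10, strict inequality).

#' Deviance information criterion of a fit
#'
#' DIC is computed on the marginal deviance, with the fixed effects and
#' genetic values integrated out and the hyperparameters
#' `theta = (log sigma_g^2, log sigma_e^2)` (only `log sigma_e^2` for
#' the null model) as the focus:
#' `D(theta) = -2 log p(y | theta)`, `DIC = 2 Dbar - D(theta_bar)` with
#' `Dbar` the posterior expectation of the deviance (grid quadrature or
#' sample average) and `theta_bar` the posterior mean on the
#' log-variance scale.  `pD = Dbar - D(theta_bar)` is the effective
#' number of hyperparameters.
#'
#' @param fit a `herit_fit`.
#' @return List with elements `dic` and `pD`.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "herit_fit"))
  list(dic = fit$dic, pD = fit$pD)
}

#' Select between the genetic and the null model by Delta-DIC
#'
#' Declares nonzero heritability when
#' `delta_dic = dic_null - dic_genetic` strictly exceeds `threshold`
#' (default 10, the conventional strong-evidence cutoff).
#'
#' @param dic_null DIC of the fixed-effects-only model.
#' @param dic_genetic DIC of the animal model.
#' @param threshold selection threshold (strict inequality).
#' @return An object of class `selection_result`: one-row data.frame
#'   with `dic_null`, `dic_genetic`, `delta_dic`, `selected`,
#'   `threshold`.
#' @export
dic_select <- function(dic_null, dic_genetic, threshold = 10) {
  stopifnot(is.finite(dic_null), is.finite(dic_genetic), is.finite(threshold))
  delta <- dic_null - dic_genetic
  structure(data.frame(dic_null = dic_null, dic_genetic = dic_genetic,
                       delta_dic = delta, selected = delta > threshold,
                       threshold = threshold),
            class = c("selection_result", "data.frame"))
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result> delta DIC = %.2f (null %.2f - genetic %.2f): %s\n",
    x$delta_dic, x$dic_null, x$dic_genetic,
    if (x$selected) sprintf("nonzero h2 (> %g)", x$threshold)
    else sprintf("no evidence (<= %g)", x$threshold)))
  invisible(x)
}
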