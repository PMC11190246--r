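## Activation functions of the perceptron layers, with their derivatives
## for backpropagation. Standard definitions: GELU uses the exact Gaussian
## CDF (not the tanh approximation); ELU has alpha = 1; SELU the usual
## lambda ~ 1.0507, alpha ~ 1.6733.

.selu_lambda <- 1.0507009873554805
.selu_alpha <- 1.6732632423543772

#' Apply an activation function
#'
#' @param name One of "relu", "elu", "gelu", "selu", "linear"
#'   (case-insensitive).
#' @param x Numeric vector or matrix; applied elementwise.
#' @return Transformed values, same shape as `x`.
#' @export
activation <- function(name, x) {
  switch(tolower(name),
    relu = pmax(x, 0),
    elu = ifelse(x > 0, x, exp(pmin(x, 0)) - 1),
    gelu = x * stats::pnorm(x),
    selu = .selu_lambda * ifelse(x > 0, x, .selu_alpha * (exp(pmin(x, 0)) - 1)),
    linear = x,
    stop("unknown activation: ", name)
  )
}

#' Derivative of an activation function
#' @inheritParams activation
#' @keywords internal
activation_grad <- function(name, x) {
  switch(tolower(name),
    relu = (x > 0) + 0,
    elu = ifelse(x > 0, 1, exp(pmin(x, 0))),
    gelu = stats::pnorm(x) + x * stats::dnorm(x),
    selu = .selu_lambda * ifelse(x > 0, 1, .selu_alpha * exp(pmin(x, 0))),
    linear = x * 0 + 1,
    stop("unknown activation: ", name)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
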