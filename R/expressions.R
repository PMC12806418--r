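# Restricted arithmetic interpreter for penetrance-cell expressions.
# Cells are formulas in two variables: x (baseline penetrance alpha) and
# y (relative penetrance f). Only +, -, *, /, ^ and parentheses are allowed;
# no function calls, so a model file can never execute code.

.pen_expr_ops <- c("+", "-", "*", "/", "^", "(")

.validate_pen_ast <- function(e, text) {
  if (is.numeric(e)) {
    if (!is.finite(e)) stop("non-finite literal in expression '", text, "'", call. = FALSE)
    return(invisible(TRUE))
  }
  if (is.symbol(e)) {
    v <- as.character(e)
    if (!v %in% c("x", "y")) {
      stop("expression '", text, "' uses variable '", v,
           "'; only 'x' (alpha) and 'y' (f) are allowed", call. = FALSE)
    }
    return(invisible(TRUE))
  }
  if (is.call(e)) {
    op <- e[[1L]]
    if (!is.symbol(op) || !as.character(op) %in% .pen_expr_ops) {
      stop("expression '", text, "' uses disallowed operator or function '",
           deparse(op), "'", call. = FALSE)
    }
    for (i in seq_along(e)[-1L]) .validate_pen_ast(e[[i]], text)
    return(invisible(TRUE))
  }
  stop("unsupported token in expression '", text, "'", call. = FALSE)
}

#' Compile a penetrance-cell expression
#'
#' Parses an arithmetic expression in the variables `x` (baseline penetrance
#' \eqn{\alpha}) and `y` (relative penetrance \eqn{f}) and returns a function
#' `function(x, y)`. The grammar is deliberately tiny: numeric literals, the
#' two variables, `+ - * / ^` and parentheses. Anything else (function calls,
#' other variables) is rejected, so untrusted model files cannot run code.
#'
#' @param text a single character string, e.g. `"x*y^2"`.
#' @return a function of two numeric arguments `x` and `y`.
#' @examples
#' f <- compile_penetrance_expr("x*y^3")
#' f(0.1, 2) # 0.8
#' @export
compile_penetrance_expr <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  e <- tryCatch(str2lang(text),
                error = function(err) stop("cannot parse expression '", text, "': ",
                                           conditionMessage(err), call. = FALSE))
  .validate_pen_ast(e, text)
  f <- function(x, y) NULL
  body(f) <- e
  environment(f) <- baseenv()
  f
}
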