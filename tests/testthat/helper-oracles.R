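# Independent oracles, written as different computational paths from the
# package implementation so that agreement is informative.

# Oracle evaluator: builds an R expression string from the tree and eval()s
# it against locally defined protected functions (vs the package's direct
# recursive switch-based walker).
oracle_eval <- function(tree, t, eps = 1e-6) {
  p_add <- function(a, b) a + b
  p_sub <- function(a, b) a - b
  p_mult <- function(a, b) a * b
  p_div <- function(a, b) {
    n <- max(length(a), length(b))
    a <- rep_len(a, n)
    b <- rep_len(b, n)
    ifelse(abs(b) > eps, a / b, 1)
  }
  p_max <- function(a, b) pmax(a, b)
  p_min <- function(a, b) pmin(a, b)
  p_sqrt <- function(a) sqrt(abs(a))
  p_log <- function(a) ifelse(abs(a) > eps, log(abs(a)), 0)
  p_abs <- function(a) abs(a)
  p_neg <- function(a) -a
  p_inv <- function(a) ifelse(abs(a) > eps, 1 / a, 1)
  p_sin <- function(a) sin(a)
  p_cos <- function(a) cos(a)
  p_tan <- function(a) pmin(pmax(tan(a), -1e6), 1e6)
  as_code <- function(node) {
    if (node$type == "var") return("t")
    if (node$type == "const") return(sprintf("(%.17g)", node$value))
    args <- vapply(node$kids, as_code, character(1))
    sprintf("p_%s(%s)", node$symbol, paste(args, collapse = ", "))
  }
  v <- eval(parse(text = as_code(tree)))
  if (length(v) == 1L) v <- rep(v, length(t))
  v
}

# Direct two-pass R-squared.
oracle_r2 <- function(obs, pred) {
  ssr <- sum((obs - pred)^2)
  sst <- sum((obs - mean(obs))^2)
  1 - ssr / sst
}

# Mann-Whitney oracle: U by direct pairwise counting (not rank sums) and the
# exact two-sided p by enumerating every assignment of pooled values.
oracle_u <- function(a, b) {
  sum(outer(a, b, function(x, y) (x > y) + 0.5 * (x == y)))
}

oracle_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  N <- length(pooled)
  mu <- n_a * length(b) / 2
  obs_dev <- abs(oracle_u(a, b) - mu)
  splits <- utils::combn(N, n_a)
  devs <- apply(splits, 2, function(ix) {
    abs(oracle_u(pooled[ix], pooled[-ix]) - mu)
  })
  mean(devs >= obs_dev - 1e-9)
}

# Random tree drawn through the package constructors but with its own
# sampling logic (used where a generic random case is needed).
random_tree_case <- function(depth, constant_range = c(-10, 10)) {
  if (depth == 0L || stats::runif(1) < 0.3) {
    if (stats::runif(1) < 0.5) return(gp_var())
    return(gp_const(stats::runif(1, constant_range[1], constant_range[2])))
  }
  sym <- sample(names(gp_function_set), 1)
  kids <- lapply(seq_len(gp_function_set[[sym]]),
                 function(i) random_tree_case(depth - 1L, constant_range))
  do.call(gp_call, c(list(sym), kids))
}

# Tidy treated-arm table from a deterministic function of time (hours).
timecourse_from_function <- function(f, times_h = c(24, 33, 43, 52, 76),
                                     n_rep = 3, cell_line = "SIM",
                                     marker = "M+") {
  grid <- expand.grid(replicate = seq_len(n_rep), time_h = times_h)
  tibble::tibble(
    cell_line = cell_line,
    marker_system = marker,
    arm = "treated",
    time_h = grid$time_h,
    replicate = as.integer(grid$replicate),
    percent = f(grid$time_h)
  )
}
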