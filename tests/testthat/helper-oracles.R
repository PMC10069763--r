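# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the package implementation.

# exhaustive nearest-neighbor scan: loops over every eligible delay vector
brute_neighbors <- function(values, E, n, tp, current_t) {
  query <- values[(current_t - E + 1):current_t]
  cand_t <- c(); cand_d <- c()
  for (ti in E:length(values)) {
    if (ti == current_t) next
    if (ti + tp > current_t) next
    x <- values[(ti - E + 1):ti]
    d <- 0
    for (k in 1:E) d <- d + (x[k] - query[k])^2
    cand_t <- c(cand_t, ti)
    cand_d <- c(cand_d, sqrt(d))
  }
  if (length(cand_t) == 0) return(NULL)
  ord <- order(cand_d, cand_t)
  keep <- ord[seq_len(min(n, length(ord)))]
  list(t_i = cand_t[keep], d_i = cand_d[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# simple trapezoid rule
trapz <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1]) / 2)

# a fixture neighbor set whose futures form two well-separated clusters:
# the query motif recurs several times, followed alternately by a low and
# a high continuation
bimodal_fixture <- function(E = 3, tp = 2, low = 0, high = 10) {
  motif <- c(5, 6, 5)
  blocks <- list()
  for (i in 1:2) {
    blocks[[length(blocks) + 1]] <- c(motif, rep(low, tp), 20, 21)
    blocks[[length(blocks) + 1]] <- c(motif, rep(high, tp), 20, 21)
  }
  values <- c(unlist(blocks), motif)
  series <- edm_series(values)
  hp <- edm_hyperparams(E = E, n = 4, tp = tp, theta = 0)
  ns <- find_neighbors(series, hp, length(values))
  list(series = series, hp = hp, ns = ns)
}

# random series + hyperparameters drawn under the ranges used throughout
random_case <- function() {
  len <- sample(50:300, 1)
  list(values = stats::rnorm(len),
       E = sample(1:8, 1),
       n = sample(1:15, 1),
       tp = sample(1:10, 1),
       len = len)
}
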