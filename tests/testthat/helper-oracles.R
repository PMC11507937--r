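# Independent brute-force oracles. These deliberately share no code with
# the package internals: plain loops, direct string comparison, explicit
# probability products without log-sum-exp shifts.

oracle_trimmed <- function(gene, t) {
  ext <- gene$extended_sequence
  n <- nchar(ext)
  if (gene$end == "V_3prime") substr(ext, 1, n - (t + 2)) else
    substr(ext, t + 3, n)
}

# independent test of every (t_v, t_j, m) triple, including the length
# constraint, against the observed junction
oracle_enumerate <- function(x, pair, trim_bounds = c(-2L, 14L),
                             m_cap = 10L) {
  out <- list()
  for (t_v in trim_bounds[1]:trim_bounds[2]) {
    vtr <- oracle_trimmed(pair$v, t_v)
    for (t_j in trim_bounds[1]:trim_bounds[2]) {
      jtr <- oracle_trimmed(pair$j, t_j)
      for (m in 0:m_cap) {
        if (m > nchar(vtr) || m > nchar(jtr)) next
        if (nchar(vtr) + nchar(jtr) - m != nchar(x)) next
        if (m > 0 &&
            substr(vtr, nchar(vtr) - m + 1, nchar(vtr)) !=
              substr(jtr, 1, m)) next
        merged <- paste0(vtr, substr(jtr, m + 1, nchar(jtr)))
        if (merged == x)
          out[[length(out) + 1L]] <- c(t_v = t_v, t_j = t_j, m = m)
      }
    }
  }
  if (length(out) == 0L) return(NULL)
  df <- as.data.frame(do.call(rbind, out))
  df <- df[order(df$t_v, df$t_j, df$m), , drop = FALSE]
  rownames(df) <- NULL
  df
}

oracle_feasible <- function(pair, t_v, t_j, m_cap = 10L) {
  vtr <- oracle_trimmed(pair$v, t_v)
  jtr <- oracle_trimmed(pair$j, t_j)
  ms <- 0L
  for (m in 1:m_cap) {
    if (m > nchar(vtr) || m > nchar(jtr)) break
    if (substr(vtr, nchar(vtr) - m + 1, nchar(vtr)) == substr(jtr, 1, m))
      ms <- c(ms, m)
  }
  ms
}

# explicit enumeration likelihood of one junction: sum over its
# annotations of P(T) * P(m | T), both computed with naive 10^x sums
oracle_sequence_lik <- function(x, pair, params, config, q = "both") {
  ann <- oracle_enumerate(x, pair, config$trim_bounds, config$m_cap)
  if (is.null(ann)) stop("oracle: unexplainable junction")
  tvals <- config$trim_bounds[1]:config$trim_bounds[2]
  scen <- expand.grid(t_v = tvals, t_j = tvals)
  score <- numeric(nrow(scen))
  for (i in seq_len(nrow(scen))) {
    fv <- trimming_feature_vector(pair, scen$t_v[i], scen$t_j[i], config)
    score[i] <- sum(fv[names(params$beta_trim)] * params$beta_trim)
  }
  p_trim_all <- 10^score / sum(10^score)
  joint_cell <- function(t_v, t_j, m) {
    ms <- oracle_feasible(pair, t_v, t_j, config$m_cap)
    w <- if (is.null(params$beta_lig)) rep(1, length(ms)) else
      10^(params$beta_lig * ms)
    p_lig <- w[match(m, ms)] / sum(w)
    p_trim_all[scen$t_v == t_v & scen$t_j == t_j] * p_lig
  }
  if (q != "both") {
    tot_q <- 0
    for (i in seq_len(nrow(scen)))
      for (m in oracle_feasible(pair, scen$t_v[i], scen$t_j[i],
                                config$m_cap))
        if (productivity(pair, scen$t_v[i], scen$t_j[i], m) == q)
          tot_q <- tot_q + joint_cell(scen$t_v[i], scen$t_j[i], m)
  }
  lik <- 0
  for (i in seq_len(nrow(ann))) {
    p <- joint_cell(ann$t_v[i], ann$t_j[i], ann$m[i])
    if (q != "both") {
      ok <- productivity(pair, ann$t_v[i], ann$t_j[i], ann$m[i]) == q
      p <- if (ok) p / tot_q else 0
    }
    lik <- lik + p
  }
  lik
}
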