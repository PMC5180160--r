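# Pure-R reference engine. Mirrors the compiled engine draw for draw (one
# uniform per stochastic entry, one per behaviour choice, one per stochastic
# kernel edge) and accumulation for accumulation, so that both engines
# produce bit-identical trajectories and value tables from the same seed.
# Used for cross-checking and for learning-rate maps; the compiled engine is
# the default for long runs.

r_run_attempts <- function(n_attempts, ct, ag, max_steps, reset_mode,
                           record, attempt_offset = 0L) {
  n_o <- ct$n_o; n_b <- ct$n_b
  reward_state <- reward_state_vec(ct)
  terminal_obs <- terminal_obs_vec(ct)
  entry_states <- ct$entry_states
  entry_cum <- ct$entry_cum
  n_entry <- length(entry_states)
  av <- ag$alpha_v; aw <- ag$alpha_w
  get_av <- function(o, c, o2) {
    if (length(av) == 1L) av
    else if (length(av) == n_o * n_b) av[o + n_o * (c - 1L)]
    else av[o + n_o * ((c - 1L) + n_b * (o2 - 1L))]
  }
  get_aw <- function(o, o2) {
    if (length(aw) == 1L) aw
    else if (length(aw) == n_o) aw[o]
    else aw[o + n_o * (o2 - 1L)]
  }

  a_entry <- integer(n_attempts); a_steps <- integer(n_attempts)
  a_ended <- integer(n_attempts); a_highest <- integer(n_attempts)
  a_total <- numeric(n_attempts); a_reached <- integer(n_attempts)
  tr <- if (record) {
    list(attempt = integer(), step = integer(), state = integer(),
         beh = integer(), nxt = integer(), u = numeric(), dv = numeric(),
         term = integer())
  }

  for (a in seq_len(n_attempts)) {
    if (n_entry > 1L) {
      r <- runif(1)
      i <- match(TRUE, r <= entry_cum, nomatch = n_entry)
      s <- entry_states[i]
    } else {
      s <- entry_states[1L]
    }
    a_entry[a] <- s
    has_dv <- FALSE; dv <- 0
    steps <- 0L; ended <- 0L; highest <- s; tot <- 0; reached <- FALSE

    repeat {
      if (steps >= max_steps) { ended <- 3L; break }
      o <- ct$obs_of[s]
      cols <- ct$rep_cols[[s]]
      b <- ag$Beta[o, cols]
      if (ag$has_mod_row[o]) {
        m0 <- ag$Mod[o, cols]
        hit <- !is.na(m0)
        if (any(hit)) b[hit] <- m0[hit] - (if (has_dv) dv else 0)
      }
      sc <- b * ag$V[o, cols]
      pe <- exp(sc - max(sc))
      S <- sum(pe)
      p <- pe / S
      cs <- cumsum(p)
      r <- runif(1)
      j <- match(TRUE, r <= cs, nomatch = length(cols))

      ns <- ct$kern_ns[[s]][[j]]
      if (length(ns) > 1L) {
        cp <- ct$kern_cp[[s]][[j]]
        r2 <- runif(1)
        i <- match(TRUE, r2 <= cp, nomatch = length(ns))
        s2 <- ns[i]
      } else {
        s2 <- ns[1L]
      }

      o2 <- ct$obs_of[s2]
      u2 <- ct$u[s2]
      term <- ct$terminal[s2]
      # attempt boundaries (terminal or reset-to-start) bootstrap from 0
      reset <- s2 == ct$start &&
        (reset_mode == 1L || (reset_mode == 2L && s != s2))
      boundary <- term || reset
      wn <- if (boundary || !ag$chaining) 0 else unname(ag$W[o2])
      cc <- cols[j]
      newdv <- unname(u2 + wn - ag$V[o, cc])
      wtarg <- unname(u2 + wn - ag$W[o])
      ag$V[o, cc] <- ag$V[o, cc] + get_av(o, cc, o2) * newdv
      if (ag$chaining && !terminal_obs[o]) {
        ag$W[o] <- ag$W[o] + get_aw(o, o2) * wtarg
      }
      tot <- tot + u2
      if (reward_state[s2]) reached <- TRUE
      if (s2 > highest) highest <- s2
      steps <- steps + 1L
      if (record) {
        tr$attempt <- c(tr$attempt, attempt_offset + a)
        tr$step <- c(tr$step, steps)
        tr$state <- c(tr$state, s)
        tr$beh <- c(tr$beh, cc)
        tr$nxt <- c(tr$nxt, s2)
        tr$u <- c(tr$u, u2)
        tr$dv <- c(tr$dv, newdv)
        tr$term <- c(tr$term, as.integer(term))
      }
      dv <- newdv; has_dv <- TRUE
      if (term) { ended <- 1L; break }
      if (reset) { ended <- 2L; break }
      s <- s2
    }
    a_steps[a] <- steps; a_ended[a] <- ended; a_highest[a] <- highest
    a_total[a] <- tot; a_reached[a] <- as.integer(reached)
  }

  out <- list(entry = a_entry, steps = a_steps, total_u = a_total,
              reached = a_reached, ended = a_ended, highest = a_highest)
  if (record) {
    out$tr_attempt <- tr$attempt; out$tr_step <- tr$step
    out$tr_state <- tr$state; out$tr_beh <- tr$beh; out$tr_next <- tr$nxt
    out$tr_u <- tr$u; out$tr_dv <- tr$dv; out$tr_term <- tr$term
  }
  out
}
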