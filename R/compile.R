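# Internal compiled representations used by the simulation engines.
#
# A compiled task is a mutable environment (training-protocol hooks edit the
# entry distribution and primary values between attempts) holding integer
# indices: states 1..n_s, observations 1..n_o, behaviour labels 1..n_b
# (columns of the value matrix V).

compile_task <- function(task) {
  stop_if_invalid(task)
  st <- task$states
  n_s <- nrow(st)
  state_names <- st$state

  obs_labels <- if (is.null(task$observe)) state_names else {
    task$observe$observation[match(state_names, task$observe$state)]
  }
  obs_names <- unique(obs_labels)
  obs_of <- match(obs_labels, obs_names)

  beh_names <- unique(task$transitions$behaviour)
  n_b <- length(beh_names)

  rep_cols <- vector("list", n_s)
  kern_ns <- vector("list", n_s)
  kern_cp <- vector("list", n_s)
  tr <- task$transitions
  tr_state <- match(tr$state, state_names)
  tr_next <- match(tr$next_state, state_names)
  tr_beh <- match(tr$behaviour, beh_names)
  for (s in seq_len(n_s)) {
    rows <- which(tr_state == s)
    if (!length(rows)) {
      rep_cols[[s]] <- integer()
      kern_ns[[s]] <- list()
      kern_cp[[s]] <- list()
      next
    }
    beh_here <- unique(tr_beh[rows])
    rep_cols[[s]] <- beh_here
    kern_ns[[s]] <- vector("list", length(beh_here))
    kern_cp[[s]] <- vector("list", length(beh_here))
    for (j in seq_along(beh_here)) {
      rr <- rows[tr_beh[rows] == beh_here[j]]
      pr <- tr$prob[rr]
      keep <- pr > 0
      rr <- rr[keep]; pr <- pr[keep]
      kern_ns[[s]][[j]] <- as.integer(tr_next[rr])
      cp <- cumsum(pr)
      cp[length(cp)] <- 1
      kern_cp[[s]][[j]] <- cp
    }
  }

  ct <- new.env(parent = emptyenv())
  ct$task <- task
  ct$n_s <- n_s
  ct$n_o <- length(obs_names)
  ct$n_b <- n_b
  ct$state_names <- state_names
  ct$obs_names <- obs_names
  ct$beh_names <- beh_names
  ct$obs_of <- as.integer(obs_of)
  ct$u <- as.numeric(st$u)
  ct$terminal <- as.logical(st$terminal)
  ct$start <- match(task$start, state_names)
  ct$reset_mode <- switch(task$attempt_closure %||% "return",
                          return = 1L, arrival = 2L)
  set_entry(ct, task$entry)
  ct$rep_cols <- rep_cols
  ct$kern_ns <- kern_ns
  ct$kern_cp <- kern_cp
  ct$meta <- task$meta
  ct
}

# entry as tibble(state, prob) -> compiled entry vectors
set_entry <- function(ct, entry) {
  if (is.character(entry)) entry <- tibble::tibble(state = entry, prob = 1)
  keep <- entry$prob > 0
  idx <- match(entry$state[keep], ct$state_names)
  cp <- cumsum(entry$prob[keep])
  cp[length(cp)] <- 1
  ct$entry_states <- as.integer(idx)
  ct$entry_cum <- as.numeric(cp)
  invisible(ct)
}

# derived, recomputed per engine call so hooks can mutate `terminal`/`u`
terminal_obs_vec <- function(ct) {
  to <- rep(FALSE, ct$n_o)
  to[ct$obs_of[ct$terminal]] <- TRUE
  to
}

reward_state_vec <- function(ct) {
  ct$terminal & ct$u > 0
}

# per-(observation, behaviour) availability: obs o has the columns of any of
# its member states (validated identical across aliased states)
obs_cols <- function(ct) {
  out <- vector("list", ct$n_o)
  for (s in seq_len(ct$n_s)) {
    o <- ct$obs_of[s]
    if (is.null(out[[o]]) && length(ct$rep_cols[[s]])) {
      out[[o]] <- ct$rep_cols[[s]]
    }
  }
  out
}

compile_agent <- function(ct, agent) {
  if (!inherits(agent, "agent_config")) {
    abort("`agent` must be an agent_config().")
  }
  n_o <- ct$n_o; n_b <- ct$n_b
  V <- matrix(0, n_o, n_b, dimnames = list(ct$obs_names, ct$beh_names))
  if (!is.null(agent$v_init)) {
    vi <- agent$v_init
    io <- match(as_chr(vi$observation), ct$obs_names)
    ib <- match(as_chr(vi$behaviour), ct$beh_names)
    if (anyNA(io) || anyNA(ib)) {
      bad <- vi[is.na(io) | is.na(ib), ]
      abort(sprintf(
        "Initial v overrides reference unknown (observation, behaviour): %s.",
        paste(sprintf("(%s, %s)", bad$observation, bad$behaviour),
              collapse = "; ")))
    }
    V[cbind(io, ib)] <- vi$value
  }

  W <- rep(0, n_o)
  names(W) <- ct$obs_names
  if (is.data.frame(agent$w_init)) {
    io <- match(as_chr(agent$w_init$observation), ct$obs_names)
    if (anyNA(io)) abort("Initial w overrides reference unknown observations.")
    W[io] <- agent$w_init$value
  } else if (agent$w_init != 0) {
    W[] <- agent$w_init
  }
  tobs <- terminal_obs_vec(ct)
  W[tobs] <- 0

  Beta <- matrix(agent$beta, n_o, n_b)
  if (!is.null(agent$beta_map)) {
    bm <- agent$beta_map
    io <- match(as_chr(bm$observation), ct$obs_names)
    ib <- match(as_chr(bm$behaviour), ct$beh_names)
    if (anyNA(io) || anyNA(ib)) {
      abort("beta_map references unknown (observation, behaviour) pairs.")
    }
    Beta[cbind(io, ib)] <- bm$beta
  }

  Mod <- matrix(NA_real_, n_o, n_b)
  if (!is.null(agent$modulation)) {
    mm <- agent$modulation
    io <- match(as_chr(mm$observation), ct$obs_names)
    ib <- match(as_chr(mm$behaviour), ct$beh_names)
    if (anyNA(io) || anyNA(ib)) {
      abort("modulation references unknown (observation, behaviour) pairs.")
    }
    Mod[cbind(io, ib)] <- mm$beta0
  }
  has_mod_row <- apply(!is.na(Mod), 1, any)

  alpha_v <- compile_rate(agent$alpha_v, agent$alpha_v_map, ct,
                          with_behaviour = TRUE)
  alpha_w <- compile_rate(agent$alpha_w, agent$alpha_w_map, ct,
                          with_behaviour = FALSE)

  ag <- new.env(parent = emptyenv())
  ag$V <- V
  ag$W <- W
  ag$Beta <- Beta
  ag$Mod <- Mod
  ag$has_mod_row <- as.logical(has_mod_row)
  ag$alpha_v <- alpha_v
  ag$alpha_w <- alpha_w
  ag$chaining <- isTRUE(agent$chaining)
  ag$config <- agent
  ag
}

# Flatten a learning-rate specification to the vector form the engines use:
# length 1 (scalar), n_o*n_b or n_o (context matrix), or the full array with
# a trailing next-observation dimension.
compile_rate <- function(default, map, ct, with_behaviour) {
  if (is.null(map)) return(as.numeric(default))
  n_o <- ct$n_o; n_b <- ct$n_b
  has_next <- "next_observation" %in% names(map)
  io <- match(as_chr(map$observation), ct$obs_names)
  if (anyNA(io)) abort("Learning-rate map references unknown observations.")
  if (with_behaviour) {
    ib <- match(as_chr(map$behaviour), ct$beh_names)
    if (anyNA(ib)) abort("Learning-rate map references unknown behaviours.")
    if (has_next) {
      a <- array(default, c(n_o, n_b, n_o))
      io2 <- match(as_chr(map$next_observation), ct$obs_names)
      if (anyNA(io2)) abort("Learning-rate map references unknown observations.")
      a[cbind(io, ib, io2)] <- map$alpha
      as.numeric(a)
    } else {
      a <- matrix(default, n_o, n_b)
      a[cbind(io, ib)] <- map$alpha
      as.numeric(a)
    }
  } else {
    if (has_next) {
      a <- matrix(default, n_o, n_o)
      io2 <- match(as_chr(map$next_observation), ct$obs_names)
      if (anyNA(io2)) abort("Learning-rate map references unknown observations.")
      a[cbind(io, io2)] <- map$alpha
      as.numeric(a)
    } else {
      a <- rep(default, n_o)
      a[io] <- map$alpha
      as.numeric(a)
    }
  }
}

v_table_from_matrix <- function(ct, V) {
  oc <- obs_cols(ct)
  rows <- lapply(seq_len(ct$n_o), function(o) {
    cols <- oc[[o]]
    if (is.null(cols) || !length(cols)) return(NULL)
    tibble::tibble(observation = ct$obs_names[o],
                   behaviour = ct$beh_names[cols],
                   value = unname(V[o, cols]))
  })
  dplyr::bind_rows(rows)
}

w_table_from_vector <- function(ct, W) {
  tibble::tibble(observation = ct$obs_names, value = as.numeric(W),
                 terminal = terminal_obs_vec(ct))
}
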