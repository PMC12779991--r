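# Prioritized experience replay. Transitions are held in a mutable buffer
# object; sampling probabilities follow P(i) = p_i^alpha / sum_k p_k^alpha
# with importance weights (N * P(i))^(-beta), normalized so the largest
# weight in a batch is 1.
#
# State vectors are stored in chunked lists: R's copy-on-modify would
# otherwise re-copy one large container on every insert that follows a
# batch read, which dominates training time at realistic capacities.

CHUNK <- 256L

chunk_of <- function(i) (i - 1L) %/% CHUNK + 1L
slot_of <- function(i) (i - 1L) %% CHUNK + 1L

#' Create an empty replay buffer
#'
#' @param capacity Maximum number of stored transitions (ring buffer).
#' @param feat_dim State feature length.
#' @return A mutable object of class `replay_buffer`.
#' @export
replay_buffer <- function(capacity = 100000L, feat_dim) {
  b <- new.env(parent = emptyenv())
  b$capacity <- as.integer(capacity)
  b$feat_dim <- as.integer(feat_dim)
  n_chunks <- chunk_of(capacity)
  b$S <- lapply(seq_len(n_chunks), function(i) vector("list", CHUNK))
  b$S2 <- lapply(seq_len(n_chunks), function(i) vector("list", CHUNK))
  b$A <- integer(capacity)
  b$R <- numeric(capacity)
  b$done <- logical(capacity)
  b$prio <- numeric(capacity)
  b$n <- 0L
  b$pos <- 0L
  b$max_prio <- 1
  class(b) <- "replay_buffer"
  b
}

#' Number of transitions currently stored
#' @param buffer A [replay_buffer()].
#' @return Integer count.
#' @export
replay_size <- function(buffer) buffer$n

#' Append one transition
#'
#' New transitions get the buffer's running maximum priority (1 if empty) so
#' every experience is sampled at least once before its TD error is known.
#'
#' @param buffer A [replay_buffer()].
#' @param state,next_state Numeric feature vectors.
#' @param action Integer action index.
#' @param reward Scalar reward.
#' @param done Terminal flag.
#' @param priority Optional explicit positive priority.
#' @return The buffer, invisibly.
#' @export
replay_add <- function(buffer, state, action, reward, next_state, done,
                       priority = NULL) {
  p <- priority %||% buffer$max_prio
  if (p <= 0) abort("priority must be positive", class = "loadctrl_invalid_input")
  buffer$max_prio <- max(buffer$max_prio, p)
  buffer$pos <- (buffer$pos %% buffer$capacity) + 1L
  i <- buffer$pos
  ci <- chunk_of(i); si <- slot_of(i)
  buffer$S[[ci]][[si]] <- as.numeric(state)
  buffer$S2[[ci]][[si]] <- as.numeric(next_state)
  buffer$A[i] <- as.integer(action)
  buffer$R[i] <- reward
  buffer$done[i] <- isTRUE(done)
  buffer$prio[i] <- p
  buffer$n <- min(buffer$n + 1L, buffer$capacity)
  invisible(buffer)
}

gather_states <- function(chunks, idx, feat_dim) {
  rows <- lapply(idx, function(i) chunks[[chunk_of(i)]][[slot_of(i)]])
  matrix(unlist(rows), length(idx), feat_dim, byrow = TRUE)
}

#' Sample a prioritized batch
#'
#' Indices are drawn with replacement with probability
#' `p_i^alpha / sum_k p_k^alpha`; importance-sampling weights are
#' `(N * P(i))^(-beta)` normalized by their in-batch maximum.
#'
#' @param buffer A [replay_buffer()].
#' @param batch_size Number of transitions to draw.
#' @param per_alpha Prioritization exponent (0 = uniform).
#' @param beta Importance-correction exponent.
#' @param stream [rng_stream()] used for the draw.
#' @param min_size Readiness threshold: the buffer must hold at least this
#'   many transitions (defaults to `batch_size`, the training semantics;
#'   sampling experiments that draw large with-replacement samples from a
#'   small buffer can lower it).
#' @return `NULL` (not-ready signal) if the buffer holds fewer than
#'   `min_size` transitions; otherwise a list with `indices`, `weights`,
#'   `states`, `actions`, `rewards`, `next_states`, `dones`.
#' @export
sample_batch <- function(buffer, batch_size, per_alpha = 0.6, beta = 0.4,
                         stream, min_size = batch_size) {
  n <- buffer$n
  if (n < min_size) return(NULL)
  pa <- buffer$prio[seq_len(n)]^per_alpha
  probs <- pa / sum(pa)
  idx <- with_stream(stream,
                     sample.int(n, batch_size, replace = TRUE, prob = probs))
  w <- (n * probs[idx])^(-beta)
  w <- w / max(w)
  list(
    indices = idx, weights = w,
    states = gather_states(buffer$S, idx, buffer$feat_dim),
    actions = buffer$A[idx],
    rewards = buffer$R[idx],
    next_states = gather_states(buffer$S2, idx, buffer$feat_dim),
    dones = buffer$done[idx]
  )
}

#' Update priorities from TD errors
#'
#' `p_i = |TD_i| + eps_p` with a small positive floor so every transition
#' keeps a nonzero sampling probability.
#'
#' @param buffer A [replay_buffer()].
#' @param indices Integer indices previously returned by [sample_batch()].
#' @param td_errors Numeric TD errors (same length).
#' @param eps_p Priority floor.
#' @return The buffer, invisibly.
#' @export
update_priorities <- function(buffer, indices, td_errors, eps_p = 1e-3) {
  if (any(indices < 1L) || any(indices > buffer$n)) {
    abort("replay index out of range", class = "loadctrl_invalid_input")
  }
  if (length(indices) != length(td_errors)) {
    abort("indices and td_errors differ in length", class = "loadctrl_invalid_input")
  }
  p <- abs(td_errors) + eps_p
  buffer$prio[indices] <- p
  buffer$max_prio <- max(buffer$max_prio, p)
  invisible(buffer)
}
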