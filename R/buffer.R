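#' Diversity-promoting experience buffer
#'
#' Stores state-action pairs from qualified trajectories (terminal score
#' above the qualification threshold). When the capacity is exceeded, the
#' entry evicted comes from the currently most frequent action key (oldest
#' first within that key), so rare actions can never be crowded out by a
#' dominant one. Sampling weights entries inversely to their action-key
#' frequency, and the imitation loss drives the policy to reproduce the
#' sampled rare actions.
#'
#' The action key defaults to the replacement residue type (20 keys);
#' position-based frequencies would be confounded by peptide length. Set
#' `keyMode = "position-residue"` for (position, residue) keys.
#'
#' @slot store Environment holding the mutable entries and counts.
#' @slot capacity Maximum number of entries.
#' @slot keyMode `"residue"` or `"position-residue"`.
#' @export
setClass("ExperienceBuffer",
  representation(store = "environment", capacity = "integer",
                 keyMode = "character"))

#' @param capacity Maximum entries retained.
#' @param keyMode Action-key granularity for frequency accounting.
#' @rdname ExperienceBuffer-class
#' @export
experienceBuffer <- function(capacity = 10000L,
                             keyMode = c("residue", "position-residue")) {
  keyMode <- match.arg(keyMode)
  store <- new.env(parent = emptyenv())
  store$entries <- list()
  store$keys <- character(0)
  store$stamp <- integer(0)   # insertion order, for oldest-first eviction
  store$clock <- 0L
  new("ExperienceBuffer", store = store, capacity = as.integer(capacity),
      keyMode = keyMode)
}

setMethod("show", "ExperienceBuffer", function(object) {
  cat("ExperienceBuffer:", bufferSize(object), "/", object@capacity,
      "entries;", length(unique(object@store$keys)), "action key(s)\n")
})

#' @rdname ExperienceBuffer-class
#' @param buffer An ExperienceBuffer.
#' @export
bufferSize <- function(buffer) length(buffer@store$entries)

#' @rdname ExperienceBuffer-class
#' @export
bufferKeyCounts <- function(buffer) {
  k <- buffer@store$keys
  if (length(k) == 0L) return(integer(0))
  table(k)
}

.actionKey <- function(buffer, position, residue) {
  if (buffer@keyMode == "residue") residue
  else paste0(position, ":", residue)
}

# evict one entry: from the most frequent key (count > 1 preferred so a
# sole entry of another key is never displaced by a dominant key), oldest
# first within the key; if every key is a singleton, evict the oldest entry
.evictOne <- function(buffer) {
  st <- buffer@store
  tab <- table(st$keys)
  cand <- names(tab)[tab > 1L]
  if (length(cand)) {
    key <- cand[which.max(tab[cand])]
    idx <- which(st$keys == key)
  } else {
    idx <- seq_along(st$keys)
  }
  victim <- idx[which.min(st$stamp[idx])]
  st$entries[[victim]] <- NULL
  st$keys <- st$keys[-victim]
  st$stamp <- st$stamp[-victim]
  invisible(NULL)
}

#' Add a qualified trajectory's state-action pairs to the buffer
#'
#' Entries are added only when the trajectory's terminal score strictly
#' exceeds the qualification threshold. Each entry stores the pre-mutation
#' state (the state in which the action was taken) and the action.
#'
#' @param buffer An [ExperienceBuffer-class] (mutated in place).
#' @param trajectory A trajectory as produced by [collectRollouts()]: a list
#'   with `peptides` (character vector of pre-mutation peptides), `allele`,
#'   `positions`, `residues` (integer alphabet indices) and `terminalScore`.
#' @param threshold Qualification threshold (shared with the environment's
#'   sigma by default).
#' @return The buffer, invisibly.
#' @export
bufferAddTrajectory <- function(buffer, trajectory, threshold = 0.75) {
  if (trajectory$terminalScore <= threshold) return(invisible(buffer))
  st <- buffer@store
  n <- length(trajectory$peptides)
  for (i in seq_len(n)) {
    entry <- list(peptide = trajectory$peptides[[i]],
                  allele = trajectory$allele,
                  step = i - 1L,
                  position = trajectory$positions[[i]],
                  residue = trajectory$residues[[i]])
    key <- .actionKey(buffer, entry$position, entry$residue)
    st$clock <- st$clock + 1L
    st$entries[[length(st$entries) + 1L]] <- entry
    st$keys <- c(st$keys, key)
    st$stamp <- c(st$stamp, st$clock)
    if (length(st$entries) > buffer@capacity) .evictOne(buffer)
  }
  invisible(buffer)
}

#' Sample entries with inverse action-frequency weights
#'
#' Each entry's weight is `1 / count(key)`, so every action key carries
#' equal total sampling mass regardless of how many entries share it.
#' Returns an empty list on an empty buffer (the imitation loss then
#' contributes 0).
#'
#' @param buffer An [ExperienceBuffer-class].
#' @param batchSize Number of entries to draw (capped at the buffer size);
#'   drawn without replacement.
#' @return List of entries.
#' @export
bufferSample <- function(buffer, batchSize) {
  st <- buffer@store
  n <- length(st$entries)
  if (n == 0L) return(list())
  tab <- table(st$keys)
  w <- 1 / as.numeric(tab[st$keys])
  k <- min(batchSize, n)
  idx <- sample.int(n, k, prob = w)
  st$entries[idx]
}
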