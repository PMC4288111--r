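# Growable in-memory tables.  Each table is an environment holding one vector
# per column plus a fill pointer; appends are O(1) amortized (capacity
# doubling), which keeps per-statement propagation fast even over long
# assert/retract sequences.  data.table views are materialized on demand for
# set-level queries and persistence.

gtab_new <- function(proto, cap = 64L) {
  g <- new.env(parent = emptyenv())
  g$.cols <- names(proto)
  g$.n <- 0L
  g$.cap <- cap
  for (nm in names(proto)) {
    v <- proto[[nm]]
    length(v) <- cap
    assign(nm, v, envir = g)
  }
  g
}

gtab_grow <- function(g, need) {
  while (g$.cap < need) {
    g$.cap <- 2L * g$.cap
    for (nm in g$.cols) {
      v <- get(nm, envir = g)
      length(v) <- g$.cap
      assign(nm, v, envir = g)
    }
  }
}

# Append one row; vals is a named list covering all columns.  Returns the row.
gtab_add <- function(g, vals) {
  i <- g$.n + 1L
  if (i > g$.cap) gtab_grow(g, i)
  g$.n <- i
  for (nm in g$.cols) {
    v <- get(nm, envir = g)
    v[i] <- vals[[nm]]
    assign(nm, v, envir = g)
  }
  i
}

# Bulk append; vals is a named list of equal-length vectors.
gtab_add_many <- function(g, vals) {
  k <- length(vals[[1L]])
  if (!k) return(invisible(integer(0)))
  i0 <- g$.n
  gtab_grow(g, i0 + k)
  g$.n <- i0 + k
  idx <- (i0 + 1L):(i0 + k)
  for (nm in g$.cols) {
    v <- get(nm, envir = g)
    v[idx] <- vals[[nm]]
    assign(nm, v, envir = g)
  }
  invisible(idx)
}

gtab_get <- function(g, col, i) get(col, envir = g)[i]

gtab_set <- function(g, col, i, val) {
  v <- get(col, envir = g)
  v[i] <- val
  assign(col, v, envir = g)
  invisible(NULL)
}

gtab_n <- function(g) g$.n

# Materialize as data.table (all physical rows).
gtab_dt <- function(g) {
  n <- g$.n
  cols <- lapply(g$.cols, function(nm) get(nm, envir = g)[seq_len(n)])
  names(cols) <- g$.cols
  data.table::as.data.table(cols)
}

gtab_copy <- function(g) {
  h <- new.env(parent = emptyenv())
  h$.cols <- g$.cols; h$.n <- g$.n; h$.cap <- g$.cap
  for (nm in g$.cols) assign(nm, get(nm, envir = g), envir = h)
  h
}

gtab_from_dt <- function(dt, proto) {
  g <- gtab_new(proto, cap = max(64L, nrow(dt)))
  if (nrow(dt)) {
    gtab_add_many(g, as.list(dt[, g$.cols, with = FALSE]))
  }
  g
}

env_copy <- function(e) {
  out <- new.env(parent = emptyenv(), hash = TRUE)
  for (nm in ls(e, all.names = TRUE)) assign(nm, get(nm, envir = e), envir = out)
  out
}
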