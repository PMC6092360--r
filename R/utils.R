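#' @importFrom rlang %||% abort warn .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# Evaluate `expr` under a private RNG stream; the caller's RNG state is
# untouched.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Deterministic 31-adic string hash into [0, 2^28); used to derive per-sample
# RNG streams that do not depend on column order.
hash_string <- function(x) {
  vapply(x, function(s) {
    h <- 0
    for (ci in utf8ToInt(s)) h <- (h * 31 + ci) %% 268435399
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# Mix a user seed with a per-unit hash, staying inside 32-bit integer range.
derive_seed <- function(seed, key) {
  as.integer((as.numeric(seed) %% 2147483647 * 7919 + hash_string(key)) %% 2147483647)
}

is_whole <- function(x, tol = 1e-8) {
  is.numeric(x) & is.finite(x) & abs(x - round(x)) < tol
}

# Extract the numeric matrix (OTUs x samples) from a wide community tibble
# whose first column is `otu_id`.
counts_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  stopifnot(is.data.frame(x), ncol(x) >= 2)
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(x[[1]])
  m
}

matrix_to_table <- function(m, id_col = "otu_id") {
  ids <- rownames(m)
  if (is.null(ids)) ids <- paste0("row", seq_len(nrow(m)))
  out <- tibble::as_tibble(as.data.frame(m, optional = TRUE),
                           .name_repair = "minimal")
  tibble::add_column(out, !!id_col := as.character(ids), .before = 1)
}

dist_to_matrix <- function(d) {
  if (inherits(d, "dist")) as.matrix(d) else as.matrix(d)
}

upper_vec <- function(m) m[upper.tri(m)]
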