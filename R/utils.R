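# Canonical module colour order, matching the convention used throughout the
# coexpression-network literature: modules are named by size rank so results
# are deterministic and comparable across runs.
.module_colors <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan", "midnightblue",
  "lightcyan", "grey60", "lightgreen", "lightyellow", "royalblue", "darkred",
  "darkgreen", "darkturquoise", "darkgrey", "orange", "darkorange", "white",
  "skyblue", "saddlebrown", "steelblue", "paleturquoise", "violet",
  "darkolivegreen", "darkmagenta"
)

#' Canonical module colour names
#'
#' Module labels are assigned by descending module size using this fixed
#' colour order ("turquoise" for the largest, then "blue", "brown", ...), with
#' "grey" reserved for unassigned background genes.
#'
#' @param n Number of colour names to return.
#' @return Character vector of colour names; if `n` exceeds the built-in
#'   palette the tail is filled with `"module<k>"` labels.
#' @export
module_colors <- function(n) {
  if (n <= length(.module_colors)) return(.module_colors[seq_len(n)])
  c(.module_colors, paste0("module", seq_len(n - length(.module_colors))))
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library code never clobbers user randomness.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Deterministic 32-bit sub-seed for a named stream, so expression, GWAS and
# gene-set simulation are independently reproducible from one global seed.
substream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 2654435) %% 2147483647)
}

stop_if_not_matrix <- function(x, arg = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  invisible(x)
}
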