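#' Fixed MOB class order
#'
#' The eleven output classes, in the fixed order used by every score vector,
#' classifier and output table in the package: the ten relaxase-defined MOB
#' families followed by the nonmobilizable category.
#'
#' @return Character vector of length 11.
#' @examples
#' mobClasses()
#' @export
mobClasses <- function() {
  c("MOBB", "MOBC", "MOBF", "MOBH", "MOBL", "MOBM",
    "MOBP", "MOBQ", "MOBT", "MOBV", "non-MOB")
}

#' Training length bins
#'
#' The four fragment-length ranges (bp), each served by its own classifier.
#'
#' @return A data.frame with columns `bin`, `lo`, `hi`.
#' @examples
#' lengthBins()
#' @export
lengthBins <- function() {
  data.frame(bin = c("B1", "B2", "B3", "B4"),
             lo = c(100L, 401L, 801L, 1201L),
             hi = c(400L, 800L, 1200L, 1600L),
             stringsAsFactors = FALSE)
}

#' Test length groups
#'
#' The four evaluation length ranges (bp) used for held-out fragments,
#' including two ranges longer than any single training bin to exercise
#' segmentation.
#'
#' @return A data.frame with columns `group`, `lo`, `hi`.
#' @export
testGroups <- function() {
  data.frame(group = c("A", "B", "C", "D"),
             lo = c(801L, 1201L, 3000L, 5000L),
             hi = c(1200L, 1600L, 4000L, 10000L),
             stringsAsFactors = FALSE)
}

# longest fragment handled by a single per-bin model; longer inputs are
# segmented
.MAX_MODEL_LEN <- 1600L

# run expr with a temporary R RNG state seeded at `seed`; restores the
# caller's state afterwards. seed = NULL leaves the RNG alone.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# all 4^k DNA tokens in lexicographic id order (id = base-4 reading, A=0)
allKmers <- function(k) {
  stopifnot(k >= 1, k <= 8)
  bases <- c("A", "C", "G", "T")
  out <- bases
  if (k > 1) for (i in 2:k) out <- as.vector(t(outer(out, bases, paste0)))
  out
}
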