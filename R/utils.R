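#' @keywords internal
"_PACKAGE"

#' Canonical season names
#'
#' The four Somali seasons in within-year order: Jilaal (long dry,
#' December--March), Gu (main rains, April--June), Hagaa (short dry,
#' July--September), Deyr (short rains, October--November). The temporal
#' index of an observation is \code{4 * (year - first_year) + season_index}
#' with season indices 0..3 in this order.
#'
#' @export
WM_SEASONS <- c("Jilaal", "Gu", "Hagaa", "Deyr")

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
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
  set.seed(as.integer(seed))
  expr
}

# Match season strings case-insensitively to the canonical names.
canonical_season <- function(x) {
  idx <- match(tolower(as.character(x)), tolower(WM_SEASONS))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))
    stop(sprintf("unknown season value(s) at position(s) %s: %s",
                 paste(utils::head(bad, 5L), collapse = ", "),
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  WM_SEASONS[idx]
}

season_index <- function(x) match(canonical_season(x), WM_SEASONS) - 1L

# numerically stable log(1 + exp(x))
log1pexp <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] + log1p(exp(-x[pos]))
  out[!pos] <- log1p(exp(x[!pos]))
  out
}

# FNV-1a hash of a character scalar, as 8 hex digits (config fingerprints).
fnv1a_hash <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "")))
  h <- 21661366  # 31-bit variant so arithmetic stays in R's integer range
  for (b in bytes) {
    h <- bitwXor(as.integer(h), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

pkg_metadata <- function(seed = NULL, config = NULL) {
  meta <- list(
    package = "wastemap",
    version = as.character(utils::packageVersion("wastemap"))
  )
  if (!is.null(seed)) meta$seed <- unname(seed)
  if (!is.null(config)) {
    meta$config_hash <- fnv1a_hash(jsonlite::toJSON(config, auto_unbox = TRUE,
                                                   force = TRUE))
  }
  meta
}
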