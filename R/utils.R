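#' @useDynLib pupilflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

pf_error <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "pf_error", "error")))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == trunc(x)
}

is_num1 <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

#' Format doubles so they parse back bit-identically
#'
#' `%.17g` is sufficient to round-trip any IEEE-754 double through text.
#' `NA`, `NaN` and infinities get dedicated tokens.
#' @param x numeric vector
#' @return character vector of the same length
#' @keywords internal
format_exact <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x) & !is.nan(x)] <- "NA"
  out[is.nan(x)] <- "NaN"
  out[is.infinite(x) & x > 0] <- "Inf"
  out[is.infinite(x) & x < 0] <- "-Inf"
  out
}

parse_exact <- function(s) {
  out <- suppressWarnings(as.numeric(s))
  out[s == "NA"] <- NA_real_
  out
}

# Canonical, locale-independent text rendering of an R value, used for
# content hashing (UWIDs, settings hashes, derived random substreams).
# Named lists are ordered by name so hash identity does not depend on
# construction order; unnamed lists keep positional order (workflow order
# is significant).
canonical_string <- function(x) {
  if (is.null(x)) return("~")
  if (is.function(x)) {
    return(paste0("f:", paste(deparse(x), collapse = "\n")))
  }
  if (is.environment(x)) pf_error("cannot hash environments", "pf_hash_error")
  if (is.raw(x)) return(paste0("r:", paste(as.character(x), collapse = "")))
  if (is.list(x) || is.data.frame(x)) {
    items <- as.list(x)
    nm <- names(items)
    if (!is.null(nm) && all(nzchar(nm))) {
      ord <- order(nm, method = "radix")
      items <- items[ord]
      nm <- nm[ord]
      body <- paste0(vapply(seq_along(items), function(i) {
        paste0(nm[i], "=", canonical_string(items[[i]]))
      }, character(1)), collapse = ";")
    } else {
      body <- paste0(vapply(items, canonical_string, character(1)),
                     collapse = ";")
    }
    return(paste0("{", body, "}"))
  }
  if (is.character(x)) {
    return(paste0("s:", paste(gsub(";", "\\;", x, fixed = TRUE),
                              collapse = "\x1f")))
  }
  if (is.logical(x)) return(paste0("b:", paste(ifelse(is.na(x), "NA",
                     ifelse(x, "T", "F")), collapse = ",")))
  if (is.integer(x)) return(paste0("i:", paste(x, collapse = ",")))
  if (is.numeric(x)) return(paste0("d:", paste(format_exact(x),
                                               collapse = ",")))
  pf_error(sprintf("cannot canonicalise object of class '%s'",
                   paste(class(x), collapse = "/")), "pf_hash_error")
}

#' MD5 of a character string (UTF-8 bytes)
#' @keywords internal
hash_string <- function(s) {
  stopifnot(is_string(s))
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(charToRaw(enc2utf8(s)), f)
  unname(tools::md5sum(f))
}

#' Content hash of an arbitrary (hashable) R value
#' @keywords internal
hash_object <- function(x) hash_string(canonical_string(x))

hash_raw <- function(bytes) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(bytes, f)
  unname(tools::md5sum(f))
}

# Derive a 31-bit integer seed from a base seed plus any number of string
# qualifiers; used for per-plugin, per-subject random substreams.
derive_seed <- function(seed, ...) {
  h <- hash_string(paste(c(as.character(seed), ...), collapse = "\x1f"))
  (strtoi(substr(h, 1, 7), 16L) + as.integer(seed %% 1024L)) %% 2147483647L
}

# Evaluate `expr` under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

base36 <- function(n, width) {
  digits <- c(0:9, letters)
  out <- character(width)
  for (i in seq_len(width)) {
    out[width - i + 1L] <- digits[(n %% 36L) + 1L]
    n <- n %/% 36L
  }
  paste(out, collapse = "")
}

# ---- tagged-value codec -----------------------------------------------------
# JSON-compatible representation in which every double is carried as a %.17g
# string, so bundle round-trips are bit-exact. Handles the value kinds the
# study model uses: NULL, atomic vectors, matrices, data frames, and (named)
# lists, preserving names and S3 class tags.

encode_payload <- function(x) {
  if (is.null(x)) return(list(t = "null"))
  atts <- list()
  cls <- attr(x, "class", exact = TRUE)
  if (is.data.frame(x)) {
    cols <- lapply(as.list(x), encode_payload)
    return(list(t = "df", names = as.list(names(x)), cols = cols,
                class = as.list(cls)))
  }
  dim <- if (is.matrix(x)) as.list(dim(x)) else NULL
  nm <- names(x)
  base <- function(t, v) {
    out <- list(t = t, v = as.list(v))
    if (!is.null(nm)) out$names <- as.list(nm)
    if (!is.null(dim)) out$dim <- dim
    if (!is.null(cls)) out$class <- as.list(cls)
    out
  }
  if (is.list(x)) {
    out <- list(t = "list", v = lapply(x, encode_payload))
    if (!is.null(nm)) out$names <- as.list(nm)
    if (!is.null(cls)) out$class <- as.list(cls)
    return(out)
  }
  if (is.character(x)) {
    out <- list(t = "chr",
                v = lapply(seq_along(x),
                           function(i) if (is.na(x[i])) NULL else x[[i]]))
    if (!is.null(nm)) out$names <- as.list(nm)
    if (!is.null(dim)) out$dim <- dim
    if (!is.null(cls)) out$class <- as.list(cls)
    return(out)
  }
  if (is.logical(x)) return(base("lgl", ifelse(is.na(x), "NA",
                                               ifelse(x, "T", "F"))))
  if (is.integer(x)) return(base("int", ifelse(is.na(x), "NA",
                                               as.character(x))))
  if (is.numeric(x)) return(base("dbl", format_exact(x)))
  if (is.raw(x)) return(base("raw", as.character(x)))
  pf_error(sprintf("cannot encode object of class '%s'",
                   paste(class(x), collapse = "/")), "pf_codec_error")
}

decode_payload <- function(e) {
  t <- e$t
  if (is.null(t)) pf_error("malformed payload: missing type tag",
                           "pf_codec_error")
  restore <- function(v) {
    if (!is.null(e$names)) names(v) <- unlist(e$names)
    if (!is.null(e$dim)) dim(v) <- unlist(e$dim)
    if (!is.null(e$class)) class(v) <- unlist(e$class)
    v
  }
  switch(t,
    null = NULL,
    chr = restore(vapply(e$v, function(s) if (is.null(s)) NA_character_
                         else as.character(s), character(1))),
    lgl = restore(vapply(e$v, function(s) switch(s, "NA" = NA,
                         "T" = TRUE, FALSE), logical(1))),
    int = restore(vapply(e$v, function(s) if (s == "NA") NA_integer_
                         else as.integer(s), integer(1))),
    dbl = restore(parse_exact(vapply(e$v, as.character, character(1)))),
    raw = restore(as.raw(as.hexmode(unlist(e$v)))),
    list = restore(lapply(e$v, decode_payload)),
    df = {
      cols <- lapply(e$cols, decode_payload)
      names(cols) <- unlist(e$names)
      df <- as.data.frame(cols, stringsAsFactors = FALSE,
                          check.names = FALSE)
      class(df) <- unlist(e$class)
      df
    },
    pf_error(sprintf("unknown payload tag '%s'", t), "pf_codec_error")
  )
}
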