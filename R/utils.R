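#' @importFrom rlang abort %||% hash
#' @import dplyr
#' @importFrom purrr map map_chr map_lgl map_int keep compact imap
#' @importFrom tibble tibble as_tibble
#' @importFrom stringr str_squish str_trim
NULL

# CURIE-style identifier: PREFIX:LOCALID
is_curie <- function(x) {
  grepl("^[A-Za-z_][A-Za-z0-9_.-]*:[A-Za-z0-9_.-]+$", x)
}

curie_prefix <- function(x) sub(":.*$", "", x)

stop_phenoxp <- function(msg, class, ...) {
  abort(msg, class = c(class, "phenoxp_error"), ...)
}

# Run code with a temporary RNG seed, restoring global RNG state afterwards.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

edge_key <- function(s, r, o) paste(s, r, o, sep = "\t")

cap_first <- function(x) {
  substr(x, 1, 1) <- toupper(substr(x, 1, 1))
  x
}

# TSV with optional '#'-prefixed provenance header lines.
write_tsv_with_header <- function(tb, path, provenance = NULL) {
  body <- readr::format_tsv(tb)
  body <- sub("\n$", "", body)
  lines <- c(
    if (length(provenance)) paste0("# ", provenance),
    strsplit(body, "\n", fixed = TRUE)[[1]]
  )
  writeLines(lines, path)
  invisible(path)
}

empty_edge_tbl <- function() {
  tibble(
    subject = character(), relation = character(), object = character(),
    status = character(), rule = character(), premises = character()
  )
}
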