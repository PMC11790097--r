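#' The default wavelet catalog
#'
#' The action space of the selection agent is an indexed catalog of 35
#' candidate mother wavelets: haar (1), db2 to db20 (2 to 20), sym3 to sym8
#' (21 to 26), sym10 (27), sym20 (28), coif3 to coif5 (29 to 31), and
#' bior1.1, bior2.2, bior3.3, bior4.4 (32 to 35).
#'
#' @return character vector of the 35 wavelet names in index order.
#' @export
default_catalog_names <- function() {
  c("haar",
    paste0("db", 2:20),
    paste0("sym", c(3:8, 10, 20)),
    paste0("coif", 3:5),
    c("bior1.1", "bior2.2", "bior3.3", "bior4.4"))
}

#' Build an indexed wavelet catalog
#'
#' Samples each requested mother wavelet by the cascade algorithm (see
#' [sample_wavelet_function()]) and assigns consecutive indices `1..Na`.
#' With no arguments the default 35-entry catalog is built, reproducing the
#' standard index assignment exactly (see [default_catalog_names()]).
#'
#' @param names optional character vector of wavelet names; defaults to the
#'   full catalog.
#' @param resolution points per unit support passed to
#'   [sample_wavelet_function()].
#' @return an object of class `wavelet_catalog`: list with `bases` (list of
#'   `wavelet_base`, indices set), `Na`, and `hash` (a digest of names and
#'   resolution used to guard checkpoint compatibility).
#' @export
#' @examples
#' cat35 <- build_catalog()
#' cat35$Na
#' catalog_table(cat35)
build_catalog <- function(names = NULL, resolution = 256) {
  names <- names %||% default_catalog_names()
  unknown <- setdiff(names, base::names(.wavelet_filter_bank))
  if (length(unknown) > 0)
    stopf("unknown wavelet name(s) in catalog spec: %s",
          paste(unknown, collapse = ", "))
  bases <- lapply(names, sample_wavelet_function, resolution = resolution)
  for (i in seq_along(bases)) bases[[i]]$index <- i
  cat <- list(
    bases = bases,
    Na = length(bases),
    resolution = resolution,
    hash = rlang::hash(list(names = names, resolution = resolution))
  )
  class(cat) <- "wavelet_catalog"
  cat
}

#' Tabulate a wavelet catalog
#'
#' @param catalog a `wavelet_catalog`.
#' @return a tibble with columns `index`, `family`, `name`,
#'   `center_frequency`.
#' @export
catalog_table <- function(catalog) {
  stopifnot(inherits(catalog, "wavelet_catalog"))
  tibble::tibble(
    index = vapply(catalog$bases, `[[`, integer(1), "index"),
    family = vapply(catalog$bases, `[[`, character(1), "family"),
    name = vapply(catalog$bases, `[[`, character(1), "name"),
    center_frequency = vapply(catalog$bases, `[[`, numeric(1), "center_frequency")
  )
}

#' Write / read a catalog definition as plain text
#'
#' The serialized form is a `index,family,name` table; reading it rebuilds
#' the catalog (wavelet functions are resampled, not stored).
#'
#' @param catalog a `wavelet_catalog`.
#' @param path file path.
#' @return `write_catalog` returns `path` invisibly; `read_catalog` returns
#'   a `wavelet_catalog`.
#' @export
write_catalog <- function(catalog, path) {
  tab <- catalog_table(catalog)[, c("index", "family", "name")]
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @param resolution passed to [build_catalog()].
#' @export
read_catalog <- function(path, resolution = 256) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("index", "name") %in% names(tab)))
    stopf("catalog file must have 'index' and 'name' columns")
  tab <- tab[order(tab$index), ]
  if (!identical(as.integer(tab$index), seq_len(nrow(tab))))
    stopf("catalog indices must be exactly 1..Na with no gaps")
  build_catalog(tab$name, resolution = resolution)
}

#' Look up a base by index or name
#' @param catalog a `wavelet_catalog`.
#' @param which integer index or wavelet name.
#' @return a `wavelet_base`.
#' @export
catalog_base <- function(catalog, which) {
  stopifnot(inherits(catalog, "wavelet_catalog"))
  if (is.character(which)) {
    i <- match(which, vapply(catalog$bases, `[[`, character(1), "name"))
    if (is.na(i)) stopf("no base named '%s' in catalog", which)
    return(catalog$bases[[i]])
  }
  which <- as.integer(which)
  if (which < 1L || which > catalog$Na)
    stopf("base index %d outside 1..%d", which, catalog$Na)
  catalog$bases[[which]]
}

#' @export
print.wavelet_catalog <- function(x, ...) {
  cat(sprintf("<wavelet_catalog> Na = %d bases, resolution %d/unit, hash %s\n",
              x$Na, x$resolution, substr(x$hash, 1, 8)))
  fam <- table(vapply(x$bases, `[[`, character(1), "family"))
  cat("  ", paste(sprintf("%s: %d", names(fam), fam), collapse = ", "), "\n")
  invisible(x)
}
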