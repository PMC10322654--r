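# Functional-group definitions used for reaction-center completion. The
# shipped list covers common biotransformation-relevant groups and is fully
# user-replaceable via a YAML file of {name, smarts} entries.

#' Load functional group definitions from YAML
#'
#' @param path YAML file: a list of entries with `name` and `smarts`.
#' @return List of functional groups with pre-parsed patterns.
#' @export
load_functional_groups <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(x) {
    list(name = x$name, smarts = x$smarts, pattern = parse_smarts(x$smarts))
  })
}

fg_cache <- new.env(parent = emptyenv())

#' Default functional group list shipped with the package
#'
#' @return List of functional groups with pre-parsed patterns.
#' @export
default_functional_groups <- function() {
  if (is.null(fg_cache$default)) {
    path <- system.file("extdata", "functional_groups.yaml", package = "ruleminer")
    if (path == "") path <- file.path("inst", "extdata", "functional_groups.yaml")
    fg_cache$default <- load_functional_groups(path)
  }
  fg_cache$default
}
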