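#' Read a condition grid from a YAML or JSON config
#'
#' The config lists the design-factor levels to cross, using the field names
#' of the simulation design: `q`, `p_per_q`, `loading`, `cross`, `phi`, `n`
#' (missing fields default to the full canonical levels), plus optional
#' `extended`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A condition tibble as from [condition_grid()].
#' @export
read_study_grid <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  # YAML 1.1 reads a bare `n:` key as boolean FALSE; map it back
  names(cfg)[names(cfg) == "FALSE"] <- "n"
  known <- c("q", "p_per_q", "loading", "cross", "phi", "n", "extended")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    abort(paste0("Unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  args <- cfg[intersect(names(cfg), known)]
  do.call(condition_grid, args)
}

# Minimal run metadata written next to every CLI output: package version,
# seeds, and input file hashes, so identical meta implies bit-identical
# deterministic outputs.
write_meta <- function(path, ..., inputs = character()) {
  meta <- list(
    package = "meantarget",
    version = as.character(utils::packageVersion("meantarget")),
    ...,
    input_md5 = lapply(inputs, function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
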