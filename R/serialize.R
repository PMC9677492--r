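# YAML/JSON round-tripping of the model definitions (tensors in MHz as
# nested 3x3 arrays).

spin_system_to_list <- function(system) {
  list(
    nuclei = lapply(seq_len(nrow(system$nuclei)), function(k) {
      list(
        label = system$nuclei$label[[k]],
        radical = system$nuclei$radical[[k]],
        spin = system$nuclei$spin[[k]],
        tensor = apply(system$nuclei$tensor[[k]], 1, as.list, simplify = FALSE)
      )
    })
  )
}

spin_system_from_list <- function(x) {
  nuc <- x$nuclei
  if (is.null(nuc) || !length(nuc)) {
    return(spin_system())
  }
  spin_system(tibble::tibble(
    label = vapply(nuc, function(n) n$label, character(1)),
    radical = vapply(nuc, function(n) n$radical, character(1)),
    spin = vapply(nuc, function(n) as.numeric(n$spin), numeric(1)),
    tensor = lapply(nuc, function(n) {
      matrix(unlist(n$tensor), 3, 3, byrow = TRUE)
    })
  ))
}

#' Write / read a spin system definition
#'
#' Serializes a [spin_system()] (nucleus labels, host radical, spin quantum
#' numbers and hyperfine tensors in MHz) to YAML or JSON; `read_spin_system`
#' reconstructs it. The embedded spin operators are rebuilt on read, so a
#' round trip reproduces the system exactly.
#'
#' @param system A [spin_system()].
#' @param path Output file; format from the extension (`.json` vs
#'   `.yaml`/`.yml`).
#' @return `write_spin_system` returns `path` invisibly;
#'   `read_spin_system` returns a `spin_system`.
#' @export
write_spin_system <- function(system, path) {
  x <- spin_system_to_list(system)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_spin_system
#' @export
read_spin_system <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  spin_system_from_list(x)
}
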