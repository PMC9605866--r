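## Selection mini-language over atom models: chain set, inclusive residue
## range, glob pattern on atom names. An empty result is an error at
## application time, not at construction.

#' Selection specification
#'
#' @param chains character vector of chain ids, or NULL for all chains.
#' @param residues inclusive residue-number range `c(start, end)`, or NULL.
#' @param pattern glob pattern on atom names (`*`, `?`), default all.
#' @return a `selection_spec` object.
#' @export
selection_spec <- function(chains = NULL, residues = NULL, pattern = "*") {
  if (!is.null(residues)) {
    stopifnot(length(residues) == 2)
    if (residues[1] > residues[2])
      stop("residue range start (", residues[1], ") > end (", residues[2], ")")
  }
  structure(list(chains = chains, residues = residues, pattern = pattern),
            class = "selection_spec")
}

#' @export
print.selection_spec <- function(x, ...) {
  cat(sprintf("<selection_spec> %s\n", format_selection(x)))
  invisible(x)
}

format_selection <- function(spec) {
  paste0(
    "chains=", if (is.null(spec$chains)) "*" else
      paste(spec$chains, collapse = ","),
    " residues=", if (is.null(spec$residues)) "*" else
      paste(spec$residues, collapse = ":"),
    " atoms=", spec$pattern)
}

#' Parse a compact selection string
#'
#' Grammar: comma/space separated clauses `chain <ids>`, `<start>:<end>`
#' (residue range), `name <glob>`; e.g. `"chain A, 74:459, name CA"`.
#'
#' @param text selection string.
#' @return a `selection_spec`.
#' @export
parse_selection <- function(text) {
  chains <- NULL; residues <- NULL; pattern <- "*"
  for (clause in trimws(strsplit(text, ",")[[1]])) {
    if (grepl("^chain\\s+", clause)) {
      chains <- strsplit(sub("^chain\\s+", "", clause), "\\s+")[[1]]
    } else if (grepl("^name\\s+", clause)) {
      pattern <- sub("^name\\s+", "", clause)
    } else if (grepl("^-?[0-9]+:-?[0-9]+$", clause)) {
      residues <- as.integer(strsplit(clause, ":")[[1]])
    } else if (nzchar(clause)) {
      stop("cannot parse selection clause: '", clause, "'")
    }
  }
  selection_spec(chains, residues, pattern)
}

#' Apply a selection to an atom model
#'
#' Atoms matching chain AND residue-range AND atom-name glob, in stable
#' order by (chain, residue number, insertion code, atom name).
#'
#' @param model an `atom_model`.
#' @param spec a `selection_spec`.
#' @return an `atom_model` subset (same columns, stable order).
#' @export
apply_selection <- function(model, spec) {
  stopifnot(inherits(model, "atom_model"), inherits(spec, "selection_spec"))
  if (nrow(model) == 0) stop("cannot select from an empty model")
  keep <- rep(TRUE, nrow(model))
  if (!is.null(spec$chains)) keep <- keep & model$chain %in% spec$chains
  if (!is.null(spec$residues))
    keep <- keep & model$resid >= spec$residues[1] &
      model$resid <= spec$residues[2]
  rx <- utils::glob2rx(spec$pattern)
  keep <- keep & grepl(rx, model$atom)
  out <- model[keep, , drop = FALSE]
  if (nrow(out) == 0)
    stop("empty selection: ", format_selection(spec))
  out <- out[order(out$chain, out$resid, out$inscode, out$atom), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, model_id = attr(model, "model_id"),
            class = c("atom_model", "data.frame"))
}
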