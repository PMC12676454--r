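#' Serialize a model back to BNGL text
#'
#' Emits the supported dialect in canonical block order. Round-trip
#' guarantee: `parse_model(write_model(m))` is structurally equal to `m`
#' (up to whitespace). Opaque `observables`/`functions` blocks are
#' re-emitted verbatim.
#'
#' @param model a `bngl_model`.
#' @param file optional path; when given the text is also written there.
#' @return the document as a single string (invisibly when `file` given).
#' @export
write_model <- function(model, file = NULL) {
  out <- c("begin model")
  if (length(model$parameters)) {
    out <- c(out, "begin parameters",
             sprintf("  %s %s", names(model$parameters), model$parameters),
             "end parameters")
  }
  if (!is.null(model$compartments) && nrow(model$compartments)) {
    out <- c(out, "begin compartments",
             sprintf("  %s %d%s", model$compartments$name,
                     model$compartments$dim,
                     ifelse(nzchar(model$compartments$rest),
                            paste0(" ", model$compartments$rest), "")),
             "end compartments")
  }
  out <- c(out, "begin molecule types",
           vapply(model$molecule_types, molecule_type_to_string, ""),
           "end molecule types")
  if (length(model$seed_species)) {
    out <- c(out, "begin seed species",
             vapply(model$seed_species, function(ss)
               sprintf("  %s %s", pattern_to_string(ss$species), ss$amount),
               ""),
             "end seed species")
  }
  if (length(model$observables)) {
    out <- c(out, "begin observables",
             paste0("  ", model$observables), "end observables")
  }
  if (length(model$functions)) {
    out <- c(out, "begin functions",
             paste0("  ", model$functions), "end functions")
  }
  out <- c(out, "begin reaction rules",
           vapply(model$rules, function(r) paste0("  ", rule_to_string(r)),
                  ""),
           "end reaction rules", "end model")
  txt <- paste(out, collapse = "\n")
  if (!is.null(file)) {
    writeLines(txt, file, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

molecule_type_to_string <- function(mt) {
  comps <- vapply(mt$components, function(cd) {
    paste0(cd$name,
           if (length(cd$states)) paste0("~", paste(cd$states, collapse = "~"))
           else "")
  }, "")
  sprintf("  %s(%s)", mt$name, paste(comps, collapse = ","))
}

component_to_string <- function(cp) {
  s <- cp$name
  if (!is.na(cp$state)) s <- paste0(s, "~", cp$state)
  else if (cp$state_wild) s <- paste0(s, "~?")
  s <- paste0(s, switch(cp$bond$kind,
                        any = "!?", none = "", plus = "!+",
                        num = paste0("!", cp$bond$index)))
  s
}

molecule_to_string <- function(mol) {
  body <- if (length(mol$comps) || mol$had_parens)
    sprintf("%s(%s)", mol$type,
            paste(vapply(mol$comps, component_to_string, ""), collapse = ","))
  else mol$type
  if (!is.na(mol$compartment)) paste0("@", mol$compartment, ":", body)
  else body
}

#' Render a complex pattern as BNGL text
#'
#' @param cx a `complex_pattern`.
#' @return a string such as `"EGF(site!1).EGFR(ecd!1,tmd)"`.
#' @export
pattern_to_string <- function(cx) {
  paste(vapply(cx$molecules, molecule_to_string, ""), collapse = ".")
}

side_to_string <- function(side) {
  if (!length(side)) return("0")
  paste(vapply(side, pattern_to_string, ""), collapse = " + ")
}

rule_to_string <- function(r) {
  arrow <- if (r$reversible) "<->" else "->"
  rates <- if (r$reversible) paste(r$rate_forward, r$rate_reverse, sep = ", ")
  else r$rate_forward
  label <- if (!is.na(r$name)) paste0(r$name, ": ") else ""
  sprintf("%s%s %s %s %s", label, side_to_string(r$reactants), arrow,
          side_to_string(r$products), rates)
}
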