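#' Parse a BNGL document
#'
#' Reads the supported BNGL dialect: `molecule types`, `parameters`,
#' `compartments`, `seed species` (synonym `species`), `observables`,
#' `functions` and `reaction rules` blocks, optionally wrapped in
#' `begin model`/`end model`. Comments start with `#`; lines ending in a
#' backslash continue on the next line. `observables` and `functions`
#' blocks are retained as opaque text. Reversible rules (`<->`) become a
#' single rule with `reversible = TRUE` and two rate expressions.
#'
#' Constructs outside the dialect (`DeleteMolecules`, `include_reactants`,
#' `exclude_reactants`, fixed species `$`) raise an error of class
#' `mpd_unsupported_error` naming the construct; malformed input raises
#' `mpd_parse_error` with the offending line number.
#'
#' @param text a single string or character vector of lines; alternatively
#'   `file` may name a file to read.
#' @param file path to a BNGL file (used when `text` is missing).
#' @param name model name recorded in provenance; defaults to the file
#'   name or "model".
#' @return a validated `bngl_model`.
#' @seealso [write_model()], [parse_pattern()]
#' @export
parse_model <- function(text, file = NULL, name = NULL) {
  if (missing(text)) {
    stopifnot(!is.null(file))
    text <- readLines(file, warn = FALSE, encoding = "UTF-8")
    if (is.null(name)) name <- sub("\\.bngl$", "", basename(file))
  }
  if (is.null(name)) name <- "model"
  lines <- preprocess_lines(text)
  blocks <- split_blocks(lines)

  mt_list <- list()
  for (ln in blocks[["molecule types"]]) {
    mol <- parse_molecule_string(strip_index_prefix(ln$text), ln$no)
    comps <- lapply(mol$comps, function(cp) {
      if (cp$bond$kind != BOND_NONE)
        parse_stop("bonds are not allowed in molecule type definitions",
                   ln$no)
      component_def(cp$name, cp$type_states)
    })
    mt_list[[length(mt_list) + 1]] <- molecule_type(mol$type, comps)
  }

  params <- character()
  for (ln in blocks[["parameters"]]) {
    m <- regmatches(ln$text,
                    regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=?\\s*(.+)$",
                            ln$text))[[1]]
    if (length(m) != 3) parse_stop("malformed parameter line", ln$no)
    params[m[2]] <- trimws(m[3])
  }

  comp_df <- NULL
  if (length(blocks[["compartments"]])) {
    rows <- lapply(blocks[["compartments"]], function(ln) {
      tok <- strsplit(trimws(ln$text), "\\s+")[[1]]
      if (length(tok) < 2) parse_stop("malformed compartment line", ln$no)
      data.frame(name = tok[1], dim = as.integer(tok[2]),
                 rest = paste(tok[-(1:2)], collapse = " "),
                 stringsAsFactors = FALSE)
    })
    comp_df <- do.call(rbind, rows)
  }

  rules <- list()
  for (ln in blocks[["reaction rules"]]) {
    rules[[length(rules) + 1]] <- parse_rule_line(ln$text, ln$no)
  }

  seeds <- list()
  for (ln in blocks[["seed species"]]) {
    txt <- strip_index_prefix(ln$text)
    if (startsWith(txt, "$")) unsupported_stop("fixed species '$'", ln$no)
    tok <- strsplit(txt, "\\s+")[[1]]
    if (length(tok) < 2)
      parse_stop("seed species line needs a pattern and an amount", ln$no)
    sp <- parse_complex_string(tok[1], ln$no)
    seeds[[length(seeds) + 1]] <-
      list(species = sp, amount = paste(tok[-1], collapse = " "))
  }

  obs <- vapply(blocks[["observables"]], `[[`, "", "text")
  fns <- vapply(blocks[["functions"]], `[[`, "", "text")

  bngl_model(molecule_types = mt_list, rules = rules, parameters = params,
             seed_species = seeds, compartments = comp_df,
             observables = obs, functions = fns, name = name)
}

# drop an optional leading integer index ("1 EGF(site) ..." style)
strip_index_prefix <- function(txt) {
  sub("^[0-9]+\\s+", "", trimws(txt))
}

preprocess_lines <- function(text) {
  raw <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  out <- list()
  i <- 1
  while (i <= length(raw)) {
    no <- i
    line <- sub("#.*$", "", raw[i])
    while (grepl("\\\\\\s*$", line) && i < length(raw)) {
      i <- i + 1
      line <- paste(sub("\\\\\\s*$", "", line),
                    sub("#.*$", "", raw[i]))
    }
    line <- trimws(line)
    i <- i + 1
    if (nzchar(line)) out[[length(out) + 1]] <- list(no = no, text = line)
  }
  out
}

BLOCK_NAMES <- c("parameters", "molecule types", "seed species", "species",
                 "observables", "functions", "reaction rules",
                 "compartments")

split_blocks <- function(lines) {
  blocks <- stats::setNames(vector("list", length(BLOCK_NAMES)), BLOCK_NAMES)
  blocks <- lapply(blocks, function(x) list())
  current <- NULL
  seen_any <- FALSE
  for (ln in lines) {
    if (grepl("^begin\\s+model$", ln$text) ||
        grepl("^end\\s+model$", ln$text)) next
    bm <- regmatches(ln$text, regexec("^begin\\s+(.+)$", ln$text))[[1]]
    if (length(bm) == 2) {
      nm <- trimws(bm[2])
      if (!nm %in% BLOCK_NAMES)
        parse_stop(sprintf("unknown block '%s'", nm), ln$no)
      if (!is.null(current)) parse_stop("nested block", ln$no)
      current <- nm
      seen_any <- TRUE
      next
    }
    em <- regmatches(ln$text, regexec("^end\\s+(.+)$", ln$text))[[1]]
    if (length(em) == 2) {
      if (is.null(current) || trimws(em[2]) != current)
        parse_stop("mismatched 'end'", ln$no)
      current <- NULL
      next
    }
    if (is.null(current))
      parse_stop(sprintf("content outside any block: '%s'", ln$text), ln$no)
    blocks[[current]] <- c(blocks[[current]], list(ln))
  }
  if (!is.null(current)) parse_stop(sprintf("unterminated block '%s'", current))
  # "species" is a synonym for "seed species"
  blocks[["seed species"]] <- c(blocks[["seed species"]], blocks[["species"]])
  if (!seen_any) parse_stop("no BNGL blocks found")
  blocks
}

# ---- pattern-level parsing ---------------------------------------------

# Parse one molecule: "@comp:Name(c1~s!1,...)" . In "molecule types" context
# multiple ~states are allowed and recorded in comp$type_states.
parse_molecule_string <- function(txt, line = NA) {
  comp <- NA_character_
  cm <- regmatches(txt, regexec("^@([A-Za-z_][A-Za-z0-9_]*):(.*)$", txt))[[1]]
  if (length(cm) == 3) {
    comp <- cm[2]
    txt <- cm[3]
  }
  m <- regmatches(txt,
        regexec("^([A-Za-z_][A-Za-z0-9_]*)(\\((.*)\\))?$", txt))[[1]]
  if (length(m) < 2 || !nzchar(m[2]))
    parse_stop(sprintf("malformed molecule '%s'", txt), line)
  had_parens <- nzchar(m[3])
  inner <- if (length(m) >= 4) m[4] else ""
  comps <- list()
  if (nzchar(inner)) {
    for (part in strsplit(inner, ",", fixed = TRUE)[[1]]) {
      comps[[length(comps) + 1]] <- parse_component_string(trimws(part), line)
    }
  }
  mol <- molecule_pattern(m[2], comps, compartment = comp,
                          had_parens = had_parens)
  mol
}

parse_component_string <- function(txt, line = NA) {
  m <- regmatches(txt, regexec(
    "^([A-Za-z_][A-Za-z0-9_]*)((?:~[A-Za-z0-9_?]+)*)(!(?:[0-9]+|\\+|\\?))?$",
    txt))[[1]]
  if (length(m) < 2 || !nzchar(m[2]))
    parse_stop(sprintf("malformed component '%s'", txt), line)
  states <- character()
  if (nzchar(m[3]))
    states <- strsplit(sub("^~", "", m[3]), "~", fixed = TRUE)[[1]]
  state <- NA_character_
  state_wild <- FALSE
  if (length(states) == 1) {
    if (states == "?") state_wild <- TRUE else state <- states
  } else if (length(states) > 1) {
    # multi-state lists only make sense in molecule type definitions;
    # keep them and let the caller decide
  }
  bond_kind <- BOND_NONE
  bond_index <- NA_integer_
  if (nzchar(m[4])) {
    b <- sub("^!", "", m[4])
    if (b == "+") bond_kind <- BOND_PLUS
    else if (b == "?") bond_kind <- BOND_ANY
    else {
      bond_kind <- BOND_NUM
      bond_index <- as.integer(b)
    }
  }
  cp <- component_pattern(m[2], state = state, state_wild = state_wild,
                          bond_kind = bond_kind, bond_index = bond_index)
  cp$type_states <- states
  cp
}

# "A(x!1).B(y!1)" -> complex_pattern (unresolved)
parse_complex_string <- function(txt, line = NA) {
  mols <- lapply(strsplit(txt, ".", fixed = TRUE)[[1]],
                 parse_molecule_string, line = line)
  # type_states lists belong to molecule type definitions only
  mols <- lapply(mols, function(mol) {
    mol$comps <- lapply(mol$comps, function(cp) {
      if (length(cp$type_states) > 1)
        parse_stop(sprintf(
          "component '%s' lists multiple states outside molecule types",
          cp$name), line)
      cp$type_states <- NULL
      cp
    })
    mol
  })
  complex_pattern(mols)
}

# split a side on top-level "+" (not the "!+" wildcard)
split_side <- function(txt, line = NA) {
  txt <- trimws(txt)
  if (txt == "0") return(list())
  shield <- gsub("!+", "!\x01", txt, fixed = TRUE)
  parts <- strsplit(shield, "+", fixed = TRUE)[[1]]
  parts <- trimws(gsub("!\x01", "!+", parts, fixed = TRUE))
  if (any(!nzchar(parts))) parse_stop("empty reactant/product term", line)
  lapply(parts, parse_complex_string, line = line)
}

# split on commas at zero parenthesis depth
split_top_commas <- function(txt) {
  depth <- 0
  cut <- integer(0)
  chars <- strsplit(txt, "")[[1]]
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "(") depth <- depth + 1
    else if (ch == ")") depth <- depth - 1
    else if (ch == "," && depth == 0) cut <- c(cut, i)
  }
  starts <- c(1, cut + 1)
  ends <- c(cut - 1, length(chars))
  vapply(seq_along(starts), function(k)
    trimws(paste(chars[seq(starts[k], ends[k])], collapse = "")), "")
}

parse_rule_line <- function(txt, line = NA) {
  for (bad in c("DeleteMolecules", "include_reactants", "exclude_reactants"))
    if (grepl(bad, txt, fixed = TRUE)) unsupported_stop(bad, line)
  # optional "Name:" label
  nm <- NA_character_
  lm <- regmatches(txt, regexec("^([A-Za-z_][A-Za-z0-9_.]*):\\s*(.*)$",
                                txt))[[1]]
  if (length(lm) == 3) {
    nm <- lm[2]
    txt <- lm[3]
  } else {
    txt <- strip_index_prefix(txt)
  }
  reversible <- grepl("<->", txt, fixed = TRUE)
  arrow <- if (reversible) "<->" else "->"
  if (!grepl(arrow, txt, fixed = TRUE))
    parse_stop("rule line has no reaction arrow", line)
  sides <- strsplit(txt, arrow, fixed = TRUE)[[1]]
  if (length(sides) != 2) parse_stop("malformed rule line", line)
  reactants <- split_side(sides[1], line)

  # right side: complexes separated by "+", then rate expression(s)
  tokens <- strsplit(trimws(sides[2]), "\\s+")[[1]]
  if (!length(tokens)) parse_stop("rule line has no products or rates", line)
  prod_txt <- tokens[1]
  k <- 2
  while (k < length(tokens) && tokens[k] == "+") {
    prod_txt <- paste0(prod_txt, "+", tokens[k + 1])
    k <- k + 2
  }
  rate_txt <- if (k <= length(tokens))
    paste(tokens[k:length(tokens)], collapse = " ") else ""
  products <- split_side(prod_txt, line)
  # bond pairing and connectivity do not need the model: check here so
  # the error still knows its line
  for (cx in c(reactants, products)) validate_complex(cx, line)
  if (!nzchar(rate_txt))
    parse_stop("rule line is missing a rate expression", line)
  rates <- split_top_commas(rate_txt)
  if (reversible && length(rates) != 2)
    parse_stop("reversible arrow requires two rate expressions", line)
  if (!reversible && length(rates) != 1)
    parse_stop("irreversible rule takes exactly one rate expression", line)
  rule(reactants, products,
       rate_forward = rates[1],
       rate_reverse = if (reversible) rates[2] else NULL,
       reversible = reversible, name = nm)
}

#' Parse a pattern string
#'
#' Convenience entry point for programmatic model construction and tests:
#' parses a single complex pattern such as `"EGF(site!1).EGFR(ecd!1,tmd)"`.
#' The result is unresolved until used inside a model; pass `model` to
#' resolve and validate it immediately.
#'
#' @param txt pattern text.
#' @param model optional `bngl_model` used to resolve component positions.
#' @return a `complex_pattern`.
#' @export
parse_pattern <- function(txt, model = NULL) {
  cx <- parse_complex_string(trimws(txt))
  if (!is.null(model)) cx <- resolve_complex(cx, model)
  cx
}
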