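#' Parse a Boolean network from BoolNet-dialect text
#'
#' Reads the comma-separated `"targets, factors"` network format: a header
#' line followed by one `gene, expression` line per gene. Expressions may use
#' `!` (NOT), `&` (AND), `|` (OR), parentheses, declared gene names, and the
#' constants `0`/`1`, with the usual NOT > AND > OR precedence. Lines starting
#' with `#` are comments. Probabilistic rules (a trailing `, probability`
#' field) and temporal extensions are rejected: the state process of a POBDS
#' requires a single deterministic network function.
#'
#' @param text A character scalar containing the whole document (newlines
#'   embedded) or a character vector of lines.
#' @return A `boolean_network` object: gene names (in declaration order) plus
#'   one parsed update rule per gene.
#' @seealso [load_network()] to read from a file, [write_boolnet()] for the
#'   inverse, [network_step()] to apply the synchronous update.
#' @examples
#' net <- parse_boolnet("targets, factors\nA, !B\nB, A")
#' network_step(net, c(0, 0))
#' @export
parse_boolnet <- function(text) {
  if (!is.character(text)) stop("'text' must be a character vector")
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  raw <- lines
  # strip comments and blank lines but remember original line numbers
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- trimws(lines[keep])
  if (length(lines) < 2L)
    stop("network document must have a 'targets, factors' header and at least one rule")
  if (!grepl("^targets\\s*,\\s*factors$", lines[1], ignore.case = TRUE))
    stop(sprintf("line %d: expected header 'targets, factors', got '%s'",
                 lineno[1], lines[1]))

  genes <- character(0)
  rule_text <- character(0)
  rule_line <- integer(0)
  for (i in seq_along(lines)[-1]) {
    ln <- lineno[i]
    comma <- regexpr(",", lines[i], fixed = TRUE)
    if (comma < 0)
      stop(sprintf("line %d: expected 'gene, expression', no comma found", ln))
    gene <- trimws(substr(lines[i], 1L, comma - 1L))
    expr <- trimws(substr(lines[i], comma + 1L, nchar(lines[i])))
    if (!nzchar(gene) || !nzchar(expr))
      stop(sprintf("line %d: empty gene name or expression", ln))
    if (grepl(",", expr, fixed = TRUE))
      stop(sprintf(paste0("line %d: extra comma in rule for '%s' -- probabilistic ",
                          "rules are an unsupported network class"), ln, gene))
    if (grepl("\\[|\\]", expr))
      stop(sprintf(paste0("line %d: temporal syntax in rule for '%s' -- ",
                          "an unsupported network class"), ln, gene))
    if (gene %in% genes)
      stop(sprintf("line %d: duplicate target gene '%s'", ln, gene))
    genes <- c(genes, gene)
    rule_text <- c(rule_text, expr)
    rule_line <- c(rule_line, ln)
  }

  rules <- vector("list", length(genes))
  names(rules) <- genes
  for (i in seq_along(genes)) {
    e <- tryCatch(str2lang(rule_text[i]),
                  error = function(err)
                    stop(sprintf("line %d: syntax error in rule for '%s': %s",
                                 rule_line[i], genes[i], conditionMessage(err)),
                         call. = FALSE))
    check_rule_ast(e, genes, rule_line[i], genes[i])
    rules[[i]] <- e
  }
  structure(list(genes = genes, rules = rules, rule_text = rule_text),
            class = "boolean_network")
}

# Walk the parsed expression; only !, &, |, ( ), gene symbols and 0/1 allowed.
check_rule_ast <- function(e, genes, line, gene) {
  bad <- function(what)
    stop(sprintf("line %d: rule for '%s': %s", line, gene, what), call. = FALSE)
  if (is.symbol(e)) {
    nm <- as.character(e)
    if (!nm %in% genes) bad(sprintf("reference to undeclared gene '%s'", nm))
    return(invisible(TRUE))
  }
  if (is.numeric(e)) {
    if (!e %in% c(0, 1)) bad(sprintf("numeric literal %s is not 0 or 1", format(e)))
    return(invisible(TRUE))
  }
  if (is.call(e)) {
    op <- as.character(e[[1]])
    if (!op %in% c("!", "&", "|", "("))
      bad(sprintf("operator '%s' is outside the supported grammar (!, &, |, parentheses)", op))
    for (k in seq_along(e)[-1]) check_rule_ast(e[[k]], genes, line, gene)
    return(invisible(TRUE))
  }
  bad("unsupported token")
}

#' Load a Boolean network from a BoolNet-format file
#'
#' @param path Path to a `"targets, factors"` text file.
#' @return A `boolean_network`.
#' @export
load_network <- function(path) {
  if (!file.exists(path)) stop(sprintf("network file not found: '%s'", path))
  parse_boolnet(readLines(path, warn = FALSE))
}

#' Serialize a Boolean network back to BoolNet text
#'
#' Deparses each rule; the output reparses to a network with an identical
#' truth table.
#'
#' @param net A `boolean_network`.
#' @param path Optional file to write to; when `NULL` the text is returned.
#' @return Invisibly (or visibly when `path` is `NULL`) the document as a
#'   character vector of lines.
#' @export
write_boolnet <- function(net, path = NULL) {
  stopifnot(inherits(net, "boolean_network"))
  txt <- c("targets, factors",
           paste0(net$genes, ", ",
                  vapply(net$rules, function(e) paste(deparse(e), collapse = " "), "")))
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @export
print.boolean_network <- function(x, ...) {
  cat(sprintf("Boolean network with %d genes\n", length(x$genes)))
  for (i in seq_along(x$genes))
    cat(sprintf("  %s <- %s\n", x$genes[i], paste(deparse(x$rules[[i]]), collapse = " ")))
  invisible(x)
}

#' Bundled p53-MDM2 network variants
#'
#' The four-gene p53-MDM2 negative feedback loop (genes ATM, p53, WIP1,
#' MDM2) with the DNA double-strand-break input baked in as a constant:
#' `dna_dsb = 0` models the unstressed cell (all four proteins decay to the
#' inactive steady state) and `dna_dsb = 1` models DNA damage, under which
#' p53 oscillates.
#'
#' @param dna_dsb 0 or 1, the constant DNA-damage input.
#' @return A `boolean_network` with genes ATM, p53, WIP1, MDM2.
#' @examples
#' find_attractors(p53_network(0))
#' @export
p53_network <- function(dna_dsb = 0) {
  if (!dna_dsb %in% c(0, 1)) stop("'dna_dsb' must be 0 or 1")
  f <- system.file("extdata", sprintf("p53net_DNAdsb%d.txt", dna_dsb),
                   package = "pobds", mustWork = TRUE)
  load_network(f)
}

# normalize a state argument to an n x d integer matrix; remembers vector input
as_state_matrix <- function(x, d, what = "x") {
  if (is.null(dim(x))) {
    if (length(x) != d)
      stop(sprintf("'%s' must have %d entries, got %d", what, d, length(x)))
    x <- matrix(x, nrow = 1L)
  } else {
    x <- as.matrix(x)
    if (ncol(x) != d)
      stop(sprintf("'%s' must have %d columns, got %d", what, d, ncol(x)))
  }
  if (!all(x %in% c(0, 1)))
    stop(sprintf("'%s' must be Boolean (entries 0/1)", what))
  storage.mode(x) <- "integer"
  x
}

#' Apply the synchronous Boolean update
#'
#' Computes the network function f: every gene's rule is evaluated on the
#' *same* input state, then all genes switch together. `x` may be a single
#' state (length-d vector) or a matrix of states (one per row), in which case
#' every row is updated independently in one vectorized pass.
#'
#' @param net A `boolean_network`.
#' @param x Boolean state vector of length d, or an n x d Boolean matrix.
#' @return Object of the same shape as `x`: the successor state(s).
#' @export
network_step <- function(net, x) {
  stopifnot(inherits(net, "boolean_network"))
  d <- length(net$genes)
  vec <- is.null(dim(x))
  xm <- as_state_matrix(x, d)
  n <- nrow(xm)
  env <- new.env(parent = baseenv())
  for (j in seq_len(d)) assign(net$genes[j], xm[, j], envir = env)
  out <- matrix(0L, n, d, dimnames = list(NULL, net$genes))
  for (j in seq_len(d)) {
    v <- eval(net$rules[[j]], env)
    v <- as.integer(as.logical(v))
    if (length(v) == 1L) v <- rep.int(v, n)
    out[, j] <- v
  }
  if (vec) out[1L, ] else out
}

#' Exhaustive attractor analysis of the noiseless dynamics
#'
#' Iterates the deterministic synchronous map from every one of the 2^d
#' states and reports all terminal cycles; length-1 cycles are reported as
#' fixed points. Because the update is a function, every state leads to
#' exactly one attractor.
#'
#' @param net A `boolean_network` with at most 20 genes.
#' @return An `attractor_report`: `fixed_points` (list of states),
#'   `cycles` (list of cycle matrices, one state per row, started at the
#'   state with the smallest index), and `basin_sizes` per attractor.
#' @export
find_attractors <- function(net) {
  stopifnot(inherits(net, "boolean_network"))
  d <- length(net$genes)
  if (d > 20) stop("state space too large to enumerate (d > 20)")
  S <- state_matrix(d)
  nxt <- encode_state(state_codec(d), network_step(net, S)) + 1L  # 1-based successor
  n_states <- 2L^d

  attr_id <- integer(n_states)            # 0 = unvisited, -1 = on current walk
  cycles_idx <- list()
  for (s in seq_len(n_states)) {
    if (attr_id[s] != 0L) next
    path <- integer(0)
    cur <- s
    while (attr_id[cur] == 0L) {
      attr_id[cur] <- -1L
      path <- c(path, cur)
      cur <- nxt[cur]
    }
    if (attr_id[cur] == -1L) {
      # closed a new cycle inside this walk
      pos <- match(cur, path)
      cyc <- path[pos:length(path)]
      rot <- which.min(cyc)               # canonical rotation
      cyc <- c(cyc[rot:length(cyc)], cyc[seq_len(rot - 1L)])
      cycles_idx[[length(cycles_idx) + 1L]] <- cyc
      attr_id[path] <- length(cycles_idx)
    } else {
      attr_id[path] <- attr_id[cur]
    }
  }

  fixed <- list(); cycles <- list()
  basin <- tabulate(attr_id, nbins = length(cycles_idx))
  fp_basin <- integer(0); cy_basin <- integer(0)
  for (k in seq_along(cycles_idx)) {
    states <- S[cycles_idx[[k]], , drop = FALSE]
    if (nrow(states) == 1L) {
      fixed[[length(fixed) + 1L]] <- stats::setNames(states[1L, ], net$genes)
      fp_basin <- c(fp_basin, basin[k])
    } else {
      colnames(states) <- net$genes
      cycles[[length(cycles) + 1L]] <- states
      cy_basin <- c(cy_basin, basin[k])
    }
  }
  structure(list(fixed_points = fixed, cycles = cycles,
                 basin_sizes = list(fixed_points = fp_basin, cycles = cy_basin),
                 genes = net$genes),
            class = "attractor_report")
}

#' @export
print.attractor_report <- function(x, ...) {
  cat(sprintf("Attractors (synchronous, noiseless): %d fixed point(s), %d cycle(s)\n",
              length(x$fixed_points), length(x$cycles)))
  for (fp in x$fixed_points)
    cat("  fixed point:", paste(fp, collapse = ""), "\n")
  for (cy in x$cycles)
    cat(sprintf("  cycle of length %d: %s\n", nrow(cy),
                paste(apply(cy, 1, paste, collapse = ""), collapse = " -> ")))
  invisible(x)
}
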