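#' @importFrom rlang abort warn
#' @importFrom stats median sd var setNames quantile
#' @importFrom utils head tail
NULL

IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L, `-` = 15L, `?` = 15L
)
BIT_BASES <- c("A", "C", "G", "T")

# ---- annotated newick ------------------------------------------------------

# Recursive-descent parser for Newick with BEAST-style [&key=value] branch
# comments, which may sit before or after the branch length. Returns a node
# table suitable for tree_from_table() plus per-node annotation list.
parse_newick_annotated <- function(text, translate = NULL) {
  s <- gsub("[\r\n]", "", text)
  pos <- 1L
  n <- nchar(s)
  rows <- list()
  next_id <- 0L

  peek <- function() substr(s, pos, pos)
  skip_ws <- function() while (pos <= n && peek() %in% c(" ", "\t")) pos <<- pos + 1L

  read_comment <- function() {
    # returns named numeric vector of scalar annotations (possibly empty)
    if (peek() != "[") return(NULL)
    depth <- 0L
    start <- pos
    repeat {
      ch <- substr(s, pos, pos)
      if (ch == "[") depth <- depth + 1L
      if (ch == "]") depth <- depth - 1L
      pos <<- pos + 1L
      if (depth == 0L || pos > n) break
    }
    body <- substr(s, start + 1L, pos - 2L)
    if (!startsWith(body, "&")) return(numeric())
    parse_annotation_body(substr(body, 2L, nchar(body)))
  }

  read_label <- function() {
    skip_ws()
    if (peek() == "'") {
      pos <<- pos + 1L
      start <- pos
      while (pos <= n && peek() != "'") pos <<- pos + 1L
      lab <- substr(s, start, pos - 1L)
      pos <<- pos + 1L
      return(lab)
    }
    start <- pos
    while (pos <= n && !peek() %in% c(",", ")", "(", ":", ";", "[", " ")) {
      pos <<- pos + 1L
    }
    substr(s, start, pos - 1L)
  }

  read_number <- function() {
    start <- pos
    while (pos <= n && grepl("[0-9eE+.\\-]", peek())) pos <<- pos + 1L
    as.numeric(substr(s, start, pos - 1L))
  }

  parse_clade <- function() {
    # returns id of node parsed; fills rows
    next_id <<- next_id + 1L
    id <- next_id
    label <- NA_character_
    skip_ws()
    kids <- integer()
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        kids <- c(kids, parse_clade())
        skip_ws()
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        abort(sprintf("malformed newick near position %d", pos))
      }
      skip_ws()
      if (!peek() %in% c(":", ",", ")", ";", "[")) label <- read_label()
    } else {
      label <- read_label()
      if (!is.null(translate)) {
        hit <- match(label, names(translate))
        if (!is.na(hit)) label <- unname(translate[hit])
      }
    }
    annot <- read_comment()
    len <- NA_real_
    skip_ws()
    if (peek() == ":") {
      pos <<- pos + 1L
      a2 <- read_comment()
      len <- read_number()
      a3 <- read_comment()
      annot <- c(annot, a2, a3)
    }
    rows[[id]] <<- list(id = id, kids = kids, label = label, len = len,
                        annot = annot)
    id
  }

  root <- parse_clade()
  list(rows = rows, root = root)
}

parse_annotation_body <- function(body) {
  # split on top-level commas (braces may nest vectors, which are skipped)
  out <- numeric()
  depth <- 0L
  pieces <- character()
  buf <- ""
  for (ch in strsplit(body, "", fixed = TRUE)[[1]]) {
    if (ch == "{") depth <- depth + 1L
    if (ch == "}") depth <- depth - 1L
    if (ch == "," && depth == 0L) {
      pieces <- c(pieces, buf); buf <- ""
    } else buf <- paste0(buf, ch)
  }
  pieces <- c(pieces, buf)
  for (p in pieces) {
    eq <- regexpr("=", p, fixed = TRUE)
    if (eq < 0) {
      warn(sprintf("malformed branch annotation '%s' skipped", p))
      next
    }
    key <- trimws(substr(p, 1, eq - 1))
    val <- trimws(substr(p, eq + 1, nchar(p)))
    num <- suppressWarnings(as.numeric(val))
    if (is.na(num)) next # vector/string annotations are ignored
    out[key] <- num
  }
  out
}

annotated_newick_to_tree <- function(text, translate = NULL) {
  parsed <- parse_newick_annotated(text, translate)
  rows <- parsed$rows
  n_all <- length(rows)
  parent <- rep(NA_integer_, n_all)
  for (r in rows) for (k in r$kids) parent[k] <- r$id
  len <- vapply(rows, function(r) r$len, numeric(1))
  len[parsed$root] <- 0
  if (anyNA(len)) abort("missing branch length in tree log")
  # depth from root, then height = max depth - depth
  depth <- numeric(n_all)
  ord <- order(is.na(parent), decreasing = TRUE) # root first then fix by loop
  # preorder by repeated passes (trees are small); root depth 0
  todo <- which(!is.na(parent))
  done <- is.na(parent)
  while (length(todo)) {
    ready <- todo[done[parent[todo]]]
    depth[ready] <- depth[parent[ready]] + len[ready]
    done[ready] <- TRUE
    todo <- setdiff(todo, ready)
  }
  labels <- vapply(rows, function(r)
    if (length(r$kids)) NA_character_ else r$label, character(1))
  height <- max(depth[!is.na(labels)]) - depth
  rate <- vapply(rows, function(r) {
    a <- r$annot
    if (!is.null(a) && "rate" %in% names(a)) unname(a[["rate"]]) else NA_real_
  }, numeric(1))
  tree_from_table(tibble::tibble(
    node = seq_len(n_all), parent = parent, height = height,
    rate = rate, label = labels
  ))
}

format_annotated_newick <- function(tree, digits = 12, node_annot = NULL) {
  # node_annot: optional list keyed by ape node id, each a named numeric
  # vector emitted as a [&k=v,...] comment on that node
  tab <- tree_table(tree)
  kids <- split(tab$node, factor(tab$parent, levels = tab$node))
  fmt_comment <- function(vals) {
    vals <- vals[!is.na(vals)]
    if (!length(vals)) return("")
    paste0("[&", paste(names(vals), format(vals, digits = digits, trim = TRUE),
                       sep = "=", collapse = ","), "]")
  }
  fmt <- function(nd) {
    ch <- kids[[nd]]
    body <- if (length(ch)) {
      paste0("(", paste(vapply(ch, fmt, character(1)), collapse = ","), ")")
    } else tab$label[nd]
    vals <- if (!is.null(node_annot) && nd <= length(node_annot)) {
      node_annot[[nd]]
    } else numeric()
    if (is.na(tab$parent[nd])) return(paste0(body, fmt_comment(vals)))
    len <- tab$height[tab$parent[nd]] - tab$height[nd]
    if (!is.na(tab$rate[nd])) vals <- c(vals, rate = tab$rate[nd])
    paste0(body, fmt_comment(vals), ":", format(len, digits = digits))
  }
  paste0(fmt(which(is.na(tab$parent))), ";")
}

# ---- traces ----------------------------------------------------------------

#' Construct a tree trace (one MCMC chain of sampled trees)
#'
#' @param trees List of `rooted_tree` objects sharing one taxon set.
#' @param iterations Strictly increasing integer iteration numbers.
#' @param chain_id Chain identifier string.
#' @param density Optional per-sample posterior log-density.
#' @return A `tree_trace`: list with elements `chain_id`, `iterations`,
#'   `trees`, `density`, `taxa`.
#' @export
tree_trace <- function(trees, iterations = seq_along(trees),
                       chain_id = "chain1", density = NULL) {
  stopifnot(length(trees) >= 1, length(iterations) == length(trees))
  if (any(diff(iterations) <= 0)) abort("iterations must be strictly increasing")
  if (!is.null(density) && length(density) != length(trees)) {
    abort("density must align with trees")
  }
  taxa <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), taxa)) {
      abort(sprintf("tree %d has a different taxon set", i))
    }
  }
  structure(
    list(chain_id = chain_id, iterations = as.integer(iterations),
         trees = trees, density = density, taxa = taxa),
    class = "tree_trace"
  )
}

#' @export
print.tree_trace <- function(x, ...) {
  cat(sprintf("Tree trace '%s': %d samples, %d taxa%s\n", x$chain_id,
              length(x$trees), length(x$taxa),
              if (is.null(x$density)) "" else ", with density"))
  invisible(x)
}

n_samples <- function(trace) length(trace$trees)

#' Burn-in and thinning sample selection
#'
#' Drops the first `ceiling(burnin_frac * M)` of `M` samples, then keeps every
#' `thin`-th of the remainder; `burnin_iter` instead drops all samples at or
#' below an absolute iteration number.
#'
#' @param iterations Integer iteration numbers of the samples.
#' @param burnin_frac Fraction of samples to discard (0 <= b < 1).
#' @param thin Keep every `thin`-th post-burnin sample.
#' @param burnin_iter Optional absolute iteration cutoff (overrides
#'   `burnin_frac`).
#' @return Integer indices of retained samples.
#' @export
burnin_indices <- function(iterations, burnin_frac = 0, thin = 1,
                           burnin_iter = NULL) {
  stopifnot(burnin_frac >= 0, burnin_frac < 1, thin >= 1)
  m <- length(iterations)
  start <- if (!is.null(burnin_iter)) {
    sum(iterations <= burnin_iter) + 1L
  } else {
    ceiling(burnin_frac * m) + 1L
  }
  if (start > m) return(integer())
  seq.int(start, m, by = thin)
}

#' Read a posterior tree log
#'
#' Reads a BEAST-style NEXUS tree log (translate table and `[&key=value]`
#' branch annotations supported, before or after branch lengths) or a plain
#' Newick file, applies burn-in and thinning, and returns a [tree_trace()].
#' Node heights are derived from branch lengths with the latest tip at
#' height 0.
#'
#' @param path File path.
#' @param format `"nexus"` or `"newick"`.
#' @inheritParams burnin_indices
#' @param chain_id Chain identifier (defaults to the file name).
#' @return A `tree_trace`.
#' @export
read_tree_log <- function(path, format = c("nexus", "newick"),
                          burnin_frac = 0, thin = 1, burnin_iter = NULL,
                          chain_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("tree log not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  chain_id <- chain_id %||% basename(path)
  if (format == "nexus") {
    translate <- parse_nexus_translate(lines)
    tree_lines <- grep("^\\s*tree\\s+", lines, ignore.case = TRUE, value = TRUE)
    if (!length(tree_lines)) abort("no tree statements found in NEXUS file")
    iters <- vapply(seq_along(tree_lines), function(i) {
      m <- regmatches(tree_lines[i],
                      regexpr("STATE_[0-9]+", tree_lines[i], ignore.case = TRUE))
      if (length(m)) as.integer(sub("STATE_", "", m, ignore.case = TRUE)) else i
    }, integer(1))
    newicks <- sub("^[^=]*=\\s*(\\[[^]]*\\]\\s*)?", "", tree_lines)
  } else {
    newicks <- lines[grepl(";", lines)]
    iters <- seq_along(newicks)
    translate <- NULL
  }
  if (any(diff(iters) <= 0)) iters <- seq_along(newicks)
  keep <- burnin_indices(iters, burnin_frac, thin, burnin_iter)
  trees <- lapply(newicks[keep], annotated_newick_to_tree, translate = translate)
  tree_trace(trees, iterations = iters[keep], chain_id = chain_id)
}

parse_nexus_translate <- function(lines) {
  i0 <- grep("^\\s*translate\\s*$", lines, ignore.case = TRUE)
  if (!length(i0)) return(NULL)
  out <- character()
  for (i in (i0[1] + 1):length(lines)) {
    ln <- trimws(lines[i])
    if (ln == ";" || grepl("^tree\\s", ln, ignore.case = TRUE)) break
    ln <- sub("[,;]\\s*$", "", ln)
    if (!nchar(ln)) next
    parts <- strsplit(ln, "\\s+")[[1]]
    lab <- gsub("^'|'$", "", paste(parts[-1], collapse = " "))
    out[parts[1]] <- lab
  }
  out
}

#' Write a tree trace as a NEXUS log
#'
#' Emits a translate table and `[&rate=...]` branch annotations so that
#' `read_tree_log()` round-trips topology, heights and annotations.
#'
#' @param trace A `tree_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_log <- function(trace, path) {
  taxa <- trace$taxa
  idx <- setNames(as.character(seq_along(taxa)), taxa)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#NEXUS", "Begin trees;", "\tTranslate"), con)
  writeLines(paste0("\t\t", seq_along(taxa), " ", taxa,
                    c(rep(",", length(taxa) - 1), "")), con)
  writeLines("\t\t;", con)
  for (i in seq_along(trace$trees)) {
    tr <- trace$trees[[i]]
    tr$tip.label <- unname(idx[tr$tip.label])
    writeLines(sprintf("tree STATE_%d = [&R] %s", trace$iterations[i],
                       format_annotated_newick(tr)), con)
  }
  writeLines("End;", con)
  invisible(path)
}

# ---- parameter logs --------------------------------------------------------

#' Read a tab-delimited MCMC parameter log
#'
#' First column must be the iteration counter (named `state`, `Sample`,
#' `iteration`, `iter` or `gen`); remaining columns are continuous series.
#' Lines starting with `#` are skipped. Returns a tibble with an `iteration`
#' column for joining to tree traces, with the chain id as an attribute.
#'
#' @param path File path.
#' @inheritParams burnin_indices
#' @param chain_id Chain identifier (defaults to the file name).
#' @return A tibble (`param_trace`) of iteration + named series.
#' @export
read_param_log <- function(path, burnin_frac = 0, burnin_iter = NULL,
                           chain_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 2) abort("parameter log has no data rows")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!tolower(header[1]) %in% c("state", "sample", "iteration", "iter", "gen")) {
    abort(sprintf("first column '%s' is not an iteration column", header[1]))
  }
  cells <- strsplit(lines[-1], "\t", fixed = TRUE)
  bad_len <- which(lengths(cells) != length(header))
  if (length(bad_len)) {
    abort(sprintf("row %d has %d fields, expected %d", bad_len[1] + 1L,
                  lengths(cells)[bad_len[1]], length(header)))
  }
  mat <- do.call(rbind, cells)
  num <- suppressWarnings(apply(mat, 2, as.numeric))
  if (is.null(dim(num))) num <- matrix(num, nrow = 1)
  bad <- which(is.na(num) & mat != "NA", arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf("non-numeric value '%s' at row %d, column '%s'",
                  mat[bad[1, 1], bad[1, 2]], bad[1, 1] + 1L, header[bad[1, 2]]))
  }
  keep <- burnin_indices(num[, 1], burnin_frac, burnin_iter = burnin_iter)
  out <- tibble::as_tibble(as.data.frame(num[keep, , drop = FALSE]),
                           .name_repair = "minimal")
  names(out) <- c("iteration", header[-1])
  if (anyDuplicated(names(out))) abort("duplicated column names in log")
  attr(out, "chain_id") <- chain_id %||% basename(path)
  class(out) <- c("param_trace", class(out))
  out
}

#' @export
write_param_log <- function(params, path) {
  df <- as.data.frame(params)
  names(df)[1] <- "state"
  cols <- lapply(df, function(x) format(x, digits = 17, trim = TRUE,
                                        scientific = FALSE))
  lines <- c(paste(names(df), collapse = "\t"),
             do.call(paste, c(cols, sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

# ---- alignments ------------------------------------------------------------

#' Read a nucleotide alignment into IUPAC state sets
#'
#' Sequences are stored as a taxa-by-sites integer matrix of 4-bit state sets
#' (A=1, C=2, G=4, T=8); IUPAC ambiguity codes expand to the corresponding
#' sets and `-`/`?`/`N` become the full set (fully missing).
#'
#' @param path File path, or `NULL` when `seqs` is given directly.
#' @param format `"fasta"` or `"nexus"`.
#' @param seqs Optional named character vector of sequences (bypasses file
#'   reading; used by the simulator).
#' @return A `dna_alignment` (integer matrix with taxon rownames).
#' @export
read_alignment <- function(path = NULL, format = c("fasta", "nexus"),
                           seqs = NULL) {
  format <- match.arg(format)
  if (is.null(seqs)) {
    chars <- if (format == "fasta") {
      x <- ape::read.FASTA(path)
      lapply(as.character(x), toupper)
    } else {
      lapply(ape::read.nexus.data(path), toupper)
    }
  } else {
    chars <- lapply(strsplit(toupper(seqs), ""), identity)
  }
  if (anyDuplicated(names(chars))) abort("duplicate sequence labels")
  lens <- lengths(chars)
  if (length(unique(lens)) != 1) {
    abort(sprintf("alignment rows have unequal lengths (%s)",
                  paste(unique(lens), collapse = ", ")))
  }
  mat <- do.call(rbind, lapply(chars, function(x) {
    bits <- IUPAC_BITS[x]
    if (anyNA(bits)) {
      abort(sprintf("unknown nucleotide code '%s'", x[which(is.na(bits))[1]]))
    }
    unname(bits)
  }))
  rownames(mat) <- names(chars)
  structure(mat, class = c("dna_alignment", "matrix", "array"))
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("DNA alignment: %d taxa x %d sites\n", nrow(x), ncol(x)))
  invisible(x)
}

#' @export
write_alignment <- function(aln, path) {
  chars <- alignment_to_chars(aln)
  writeLines(as.vector(rbind(paste0(">", rownames(aln)),
                             vapply(chars, paste, character(1), collapse = ""))),
             path)
  invisible(path)
}

alignment_to_chars <- function(aln) {
  code <- rep("N", 15)
  for (nm in names(IUPAC_BITS)) {
    if (!nm %in% c("U", "?", "-")) code[IUPAC_BITS[[nm]]] <- nm
  }
  lapply(seq_len(nrow(aln)), function(i) code[aln[i, ]])
}

#' Read tip metadata (sampling dates, locations)
#'
#' Tab-separated file with columns `taxon`, `date` (decimal year) and
#' optionally `location`.
#'
#' @param path File path.
#' @return A tibble with columns `taxon`, `date`, `location`.
#' @export
read_tip_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("taxon", "date") %in% names(df))) {
    abort("tip metadata needs 'taxon' and 'date' columns")
  }
  if (!is.numeric(df$date)) abort("'date' column must be numeric decimal years")
  if (is.null(df$location)) df$location <- NA_character_
  tibble::as_tibble(df[c("taxon", "date", "location")])
}
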