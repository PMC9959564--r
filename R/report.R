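# Report writers and readers: ranked dot-bracket text, machine-readable
# JSON, and standard CT connectivity tables (circular: the backbone
# closes, so position N connects back to 1).

#' Render a prediction report
#'
#' @param fit A [circfold()] result.
#' @param format `"text"` (header plus ranked dot-bracket lines),
#'   `"json"` (full machine-readable report with both energy measures and
#'   signature flags) or `"ct"` (one connectivity table per structure).
#' @param file Optional path. For `"ct"` a path is used as a prefix
#'   (`<prefix>_<rank>.ct`); with `file = NULL` the rendering is
#'   returned.
#' @return Invisibly (or visibly when `file = NULL`) the rendered output:
#'   a character vector for text, a JSON string, or a list of CT
#'   character vectors.
#' @export
write_report <- function(fit, format = c("text", "json", "ct"),
                         file = NULL) {
  stopifnot(inherits(fit, "circfold"))
  format <- match.arg(format)
  out <- switch(format,
                text = .report_text(fit),
                json = .report_json(fit),
                ct = .report_ct(fit))
  if (is.null(file)) return(out)
  if (format == "ct") {
    for (r in seq_along(out))
      writeLines(out[[r]], sprintf("%s_%d.ct", sub("\\.ct$", "", file), r))
  } else if (format == "json") {
    writeLines(out, file)
  } else {
    writeLines(out, file)
  }
  invisible(out)
}

.report_text <- function(fit) {
  cons <- if (length(fit$constraints) == 0L) "none"
          else paste(vapply(fit$constraints, .constraint_label, character(1)),
                     collapse = "; ")
  lines <- c(
    "# circfold prediction report",
    sprintf("# name: %s", fit$sequence$name),
    sprintf("# length: %d nt (circular)", fit$sequence$n),
    sprintf("# temperature: %.2f C", fit$model$temperature_celsius),
    sprintf("# constraints: %s", cons),
    sprintf("# structures: %d", length(fit$results)),
    sprintf("SEQUENCE %s", as.character(fit$sequence)))
  if (any(vapply(fit$results, function(r) origin_spanning(r$structure),
                 logical(1))))
    lines <- c(lines,
      "# note: helices spanning the sequence origin are present; pairing is circular")
  for (r in seq_along(fit$results)) {
    res <- fit$results[[r]]
    lines <- c(lines, sprintf("%d %s %.2f %s", r, dot_bracket(res$structure),
                              res$free_energy,
                              signature_label(res$signature)))
  }
  lines
}

.report_json <- function(fit) {
  obj <- list(
    name = fit$sequence$name,
    length = fit$sequence$n,
    sequence = as.character(fit$sequence),
    temperature_celsius = fit$model$temperature_celsius,
    constraints = vapply(fit$constraints, .constraint_label, character(1)),
    structures = lapply(seq_along(fit$results), function(r) {
      res <- fit$results[[r]]
      list(rank = r,
           dot_bracket = dot_bracket(res$structure),
           pairs = res$structure$pairs,
           free_energy = res$free_energy,
           ensemble_free_energy = res$ensemble_free_energy,
           signature = signature_label(res$signature),
           included = if (length(res$signature$flags)) res$signature$flags
                      else logical(0),
           origin_spanning = origin_spanning(res$structure))
    }))
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
}

.report_ct <- function(fit) {
  seq <- fit$sequence
  n <- seq$n
  lapply(seq_along(fit$results), function(r) {
    res <- fit$results[[r]]
    partner <- integer(n)
    pr <- res$structure$pairs
    if (nrow(pr) > 0L) {
      partner[pr[, 1]] <- pr[, 2]
      partner[pr[, 2]] <- pr[, 1]
    }
    head <- sprintf("%5d dG = %.2f  %s (circular)", n, res$free_energy,
                    seq$name)
    # circular backbone: the 3' neighbor of N is 1
    body <- vapply(seq_len(n), function(p)
      sprintf("%5d %s %7d %7d %7d %7d", p, seq$bases[p], p - 1L,
              if (p == n) 1L else p + 1L, partner[p], p),
      character(1))
    c(head, body)
  })
}

#' Re-parse a text report
#'
#' @param lines Character vector as produced by
#'   `write_report(fit, "text")`.
#' @return A list with `sequence`, `structures` (list of
#'   [secondary_structure()]) and `energies`.
#' @export
parse_report_text <- function(lines) {
  seqline <- grep("^SEQUENCE ", lines, value = TRUE)
  if (length(seqline) != 1L) stop("malformed report: no SEQUENCE line",
                                  call. = FALSE)
  s <- sub("^SEQUENCE ", "", seqline)
  rows <- grep("^[0-9]+ [.()]+ ", lines, value = TRUE)
  structures <- list()
  energies <- numeric(0)
  for (row in rows) {
    toks <- strsplit(row, " ")[[1]]
    structures[[length(structures) + 1L]] <- parse_dot_bracket(toks[2])
    energies <- c(energies, as.numeric(toks[3]))
  }
  list(sequence = s, structures = structures, energies = energies)
}

#' Read a CT connectivity table
#'
#' @param lines Character vector (one CT record) or a file path.
#' @return A list with `sequence`, `structure`
#'   ([secondary_structure()]) and `energy` (parsed from the header when
#'   present).
#' @export
read_ct <- function(lines) {
  if (length(lines) == 1L && file.exists(lines)) lines <- readLines(lines)
  head <- lines[1]
  n <- as.integer(strsplit(trimws(head), "[[:space:]]+")[[1]][1])
  energy <- suppressWarnings(
    as.numeric(sub(".*dG = ([-0-9.]+).*", "\\1", head)))
  body <- lines[-1][seq_len(n)]
  toks <- strsplit(trimws(body), "[[:space:]]+")
  bases <- vapply(toks, `[[`, character(1), 2)
  partner <- vapply(toks, function(t) as.integer(t[5]), integer(1))
  pairs <- which(partner > seq_len(n))
  pm <- cbind(pairs, partner[pairs])
  list(sequence = paste(bases, collapse = ""),
       structure = secondary_structure(pm, n), energy = energy)
}
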