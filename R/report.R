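# Markdown rendering of a pipeline bundle: segment/count/percentage tables,
# cross-state matrices with flagged minima, and energy summaries.

md_table <- function(df, digits = 2) {
  fmt <- function(v) {
    if (is.numeric(v)) formatC(v, digits = digits, format = "f") else
      as.character(v)
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}

#' Render a pipeline bundle as Markdown tables
#'
#' Missing stages are listed as absent rather than failing, so partial
#' bundles render.
#'
#' @param bundle an `mt_report_bundle` from [run_pipeline()], possibly
#'   partial.
#' @param path optional output file; when `NULL` the text is returned only.
#' @return Character vector of Markdown lines, invisibly when written.
#' @export
render_report <- function(bundle, path = NULL) {
  out <- c("# Binder-filament association report", "")
  absent <- character(0)

  if (!is.null(bundle$contacts) && nrow(bundle$contacts) > 0) {
    out <- c(out, "## Mean tail-binder contacts by offset", "",
             md_table(bundle$contacts), "")
  } else absent <- c(absent, "contacts")

  if (!is.null(bundle$contact_tables) && length(bundle$contact_tables) > 0) {
    seg <- bundle$contact_tables[[1]]$per_segment
    seg <- seg[seg$n_contacts > 0 | seg$percentage > 0, ]
    if (nrow(seg) > 0) {
      out <- c(out, "## Contacts by binder segment (bound state)", "",
               md_table(seg), "")
    }
  } else absent <- c(absent, "segment table")

  if (!is.null(bundle$rmsf) && nrow(bundle$rmsf) > 0) {
    out <- c(out, "## Mean RMSF by offset", "", md_table(bundle$rmsf, 3), "")
    if (!is.null(bundle$rmsf_fits)) {
      fits <- bind_rows(
        mutate(glance(bundle$rmsf_fits$distance), predictor = "offset"),
        mutate(glance(bundle$rmsf_fits$contacts), predictor = "contacts"))
      out <- c(out, "### RMSF trend fits", "", md_table(fits, 4), "")
    }
  } else absent <- c(absent, "rmsf")

  if (!is.null(bundle$cross_state)) {
    long <- tidy(bundle$cross_state)
    long$rmsd <- ifelse(long$is_col_min,
                        sprintf("**%.2f**", long$rmsd),
                        sprintf("%.2f", long$rmsd))
    wide <- tidyr::pivot_wider(long[, c("free", "bound", "rmsd")],
                               names_from = "bound", names_prefix = "bound",
                               values_from = "rmsd")
    out <- c(out, "## Free vs bound cluster RMSD (Å; bold = column minimum)",
             "", md_table(wide), "")
  } else absent <- c(absent, "cross-state matrix")

  if (!is.null(bundle$energy) && nrow(bundle$energy) > 0) {
    en <- bundle$energy
    en$summary <- sprintf("%.2f ± %.2f", en$de_binding, en$sd)
    out <- c(out, "## Rigid-body binding energy (kcal/mol)", "",
             md_table(en[, c("tails", "e_complex", "e_part_a", "e_part_b",
                             "summary", "n_snapshots")]), "")
  } else absent <- c(absent, "energy")

  if (length(absent) > 0) {
    out <- c(out, "## Absent stages", "",
             paste0("- ", absent), "")
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
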