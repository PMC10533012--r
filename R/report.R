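#' Scientific-notation cell formatting
#'
#' Two-significant-digit scientific notation in the publication style,
#' e.g. `1.234e-3` with pooled SD `5.6e-4` prints as
#' `"1.2 x 10^-3 +/- 5.6 x 10^-4"`.
#'
#' @param x Numeric scalar.
#' @return Character scalar (`"0"` for exact zero).
#' @export
format_sci <- function(x) {
  if (is.na(x)) return("NA")
  if (x == 0) return("0")
  e <- floor(log10(abs(x)))
  m <- x / 10^e
  # keep the mantissa in [1, 10) after rounding
  if (round(abs(m), 1) >= 10) { m <- m / 10; e <- e + 1 }
  sprintf("%.1f x 10^%d", m, e)
}

format_estimate <- function(est, sd) {
  sprintf("%s +/- %s", format_sci(est), format_sci(sd))
}

#' Render publication-style report tables
#'
#' One table per response: term, estimate with Rubin pooled SD, mean and SD
#' of per-imputation p-values, the 80% trimmed-mean p-value, significance
#' markers (`*` for mean p <= 0.05 — the bold convention — and a dagger
#' `+` for trimmed mean p <= 0.05), and the adjusted R-squared mean and SD.
#' Also writes the round-1 per-criterion variable selections and a run
#' manifest (seed, m, configuration).
#'
#' @param result A [run_pipeline()] result.
#' @param dir Output directory.
#' @param format `"csv"`, `"markdown"`, or both.
#' @return Invisible character vector of the files written.
#' @export
render_report <- function(result, dir, format = c("csv", "markdown")) {
  format <- match.arg(format, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (resp in names(result$round2)) {
    pooled <- result$round2[[resp]]$pooled
    df <- pooled$terms
    tab <- data.frame(
      term = df$term,
      estimate = df$estimate,
      pooled_sd = df$pooled_sd,
      estimate_fmt = mapply(format_estimate, df$estimate, df$pooled_sd),
      p_mean = df$p_mean,
      p_sd = df$p_sd,
      p_trimmed = df$p_trimmed,
      marker = paste0(ifelse(df$primary, "*", ""),
                      ifelse(df$secondary, "+", "")),
      presence = df$presence,
      stringsAsFactors = FALSE)
    safe <- gsub("[^A-Za-z0-9_.-]", "_", resp)
    if ("csv" %in% format) {
      f <- file.path(dir, paste0("final_", safe, ".csv"))
      write.csv(tab, f, row.names = FALSE, quote = FALSE)
      files <- c(files, f)
    }
    if ("markdown" %in% format) {
      f <- file.path(dir, paste0("final_", safe, ".md"))
      lines <- c(
        sprintf("## %s", resp),
        "",
        sprintf("Adjusted R^2: %.3f +/- %.3f (m = %d)", pooled$r2_mean,
                pooled$r2_sd, pooled$m),
        "",
        "| Term | Estimate +/- pooled SD* | p (mean +/- SD)** | Trimmed p |",
        "|---|---|---|---|",
        sprintf("| %s | %s | %s%.3f +/- %.3f%s%s | %.3f |",
                tab$term, tab$estimate_fmt,
                ifelse(df$primary, "**", ""), tab$p_mean, tab$p_sd,
                ifelse(df$primary, "**", ""),
                ifelse(df$secondary, " †", ""),
                tab$p_trimmed),
        "",
        paste("\\* Pooled standard deviation (Rubin's rule).",
              "\\*\\* Bold: mean p-value <= 0.05;",
              "†: 80% trimmed mean of p-values <= 0.05."))
      writeLines(lines, f)
      files <- c(files, f)
    }
  }
  sel <- list()
  for (resp in names(result$round1)) {
    pc <- result$round1[[resp]]$per_criterion
    for (cr in names(pc)) {
      if (length(pc[[cr]])) {
        sel[[length(sel) + 1L]] <- data.frame(
          response = resp, criterion = cr, variable = pc[[cr]],
          stringsAsFactors = FALSE)
      }
    }
  }
  f <- file.path(dir, "round1_selection.csv")
  write.csv(if (length(sel)) do.call(rbind, sel) else
    data.frame(response = character(), criterion = character(),
               variable = character()),
    f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)
  mf <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(seed = result$seed, m = result$m,
                        responses = names(result$round2),
                        config = result$config), mf)
  files <- c(files, mf)
  invisible(files)
}
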