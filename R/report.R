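## Pre/post comparison reporting: ROM and stress-maxima ratio tables,
## mobility shares, and model-vs-radiograph angle validation summaries.
## Rounding conventions: percentages to 1 decimal, "times" ratios to 2
## significant figures.

pct1 <- function(x) round(100 * x, 1)
times2 <- function(x) signif(x, 2)

#' Pre/post comparison report
#'
#' Joins two summaries on `scope` and reports post/pre ratios, both as a
#' percentage (1 decimal) and as a "times" factor (2 significant
#' figures), plus the direction of change.  Rows with non-positive pre
#' values are flagged and carry no ratio.
#'
#' @param pre_summary,post_summary data.frames with columns `scope` and
#'   `value` (same scopes in both).
#' @return data.frame of class `comparison_report` with columns `scope`,
#'   `pre`, `post`, `ratio`, `percent`, `times`, `direction`, `flag`.
#' @export
compare_summaries <- function(pre_summary, post_summary) {
  if (!setequal(pre_summary$scope, post_summary$scope)) {
    stop("scope mismatch between pre and post summaries: ",
         paste(union(setdiff(pre_summary$scope, post_summary$scope),
                     setdiff(post_summary$scope, pre_summary$scope)),
               collapse = ", "))
  }
  post <- post_summary$value[match(pre_summary$scope, post_summary$scope)]
  pre <- pre_summary$value
  ok <- pre > 0
  ratio <- ifelse(ok, post / pre, NA_real_)
  out <- data.frame(
    scope = pre_summary$scope, pre = pre, post = post, ratio = ratio,
    percent = ifelse(ok, pct1(ratio), NA_real_),
    times = ifelse(ok, times2(ratio), NA_real_),
    direction = ifelse(!ok, NA_character_,
                       ifelse(abs(post - pre) < 1e-12, "unchanged",
                              ifelse(post > pre, "increase", "decrease"))),
    flag = ifelse(ok, "", "nonpositive pre value"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("comparison_report", "data.frame")
  out
}

segment_range <- function(seg, levels) {
  lv <- parse_segment(seg)
  i <- match(lv, levels)
  if (anyNA(i)) stop("unknown level in segment ", seg)
  sort(i)
}

#' Mobility share of a block
#'
#' `100 * ROM(block) / ROM(total)`, 1-decimal rounding, where the total
#' is the sum of the provided non-overlapping blocks.  Blocks that
#' overlap in more than a shared boundary vertebra (e.g. counting
#' T9-T10 inside C7-T10 twice) are an error.
#'
#' @param rom_rows data.frame with columns `scope` (segment labels like
#'   `"C7-T10"`) and `value` (ROM, degrees); the blocks must tile the
#'   spine without interior overlap.
#' @param block the scope whose share is reported.
#' @param levels ordered level labels used to parse segment ranges.
#' @return share in percent (1 decimal).
#' @export
mobility_share <- function(rom_rows, block, levels = spine_levels(18)) {
  rng <- lapply(rom_rows$scope, segment_range, levels = levels)
  n <- length(rng)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        lo <- max(rng[[i]][1], rng[[j]][1])
        hi <- min(rng[[i]][2], rng[[j]][2])
        if (hi - lo > 0) {
          stop("overlapping blocks: ", rom_rows$scope[i], " and ",
               rom_rows$scope[j])
        }
      }
    }
  }
  total <- sum(rom_rows$value)
  if (total <= 0) stop("total ROM must be > 0")
  i <- match(block, rom_rows$scope)
  if (is.na(i)) stop("block not among the ROM rows: ", block)
  pct1(rom_rows$value[i] / total)
}

#' Model-vs-radiograph angle validation summary
#'
#' @param model_angles,radiograph_angles data.frames with columns
#'   `angle` (e.g. "Cobb", "TLK"), `timepoint` (e.g. "pre", "post") and
#'   `value_deg`; every (angle, timepoint) pair must be present in both.
#' @return data.frame with the paired values and absolute discrepancies
#'   (degrees).
#' @export
validation_summary <- function(model_angles, radiograph_angles) {
  key <- function(d) paste(d$angle, d$timepoint)
  if (!setequal(key(model_angles), key(radiograph_angles))) {
    stop("missing angle/timepoint pair between model and radiograph")
  }
  i <- match(key(model_angles), key(radiograph_angles))
  data.frame(angle = model_angles$angle,
             timepoint = model_angles$timepoint,
             model_deg = model_angles$value_deg,
             radiograph_deg = radiograph_angles$value_deg[i],
             discrepancy_deg = abs(model_angles$value_deg -
                                     radiograph_angles$value_deg[i]),
             stringsAsFactors = FALSE)
}

#' ROM summary rows for a solved model
#'
#' @param spine a `spine_mesh`; @param result a `solve_result`.
#' @param blocks segment labels (`"upper-lower"`).
#' @return data.frame with columns `scope`, `value` (degrees).
#' @export
rom_summary <- function(spine, result,
                        blocks = c("C7-T10", "T10-L4", "L4-L5")) {
  data.frame(scope = blocks,
             value = vapply(blocks, function(b) {
               segment_rom_value(spine, result, b)
             }, numeric(1)),
             stringsAsFactors = FALSE)
}

#' Stress-maxima summary rows for a solved model
#'
#' @param spine a `spine_mesh`; @param result a `solve_result`.
#' @param endplates list of `c(level, side)` pairs.
#' @param annuli segment labels.
#' @return data.frame with columns `scope`, `value` (kPa).
#' @export
stress_summary <- function(spine, result,
                           endplates = list(c("T10", "sup"),
                                            c("L4", "inf")),
                           annuli = c("T9-T10", "L4-L5")) {
  rows <- lapply(endplates, function(ep) {
    v <- stress_maxima(spine, result, list(type = "endplate",
                                           level = ep[1], side = ep[2]))
    data.frame(scope = paste0("endplate:", ep[1], "_", ep[2]),
               value = v$max_kpa, stringsAsFactors = FALSE)
  })
  rows <- c(rows, lapply(annuli, function(seg) {
    v <- stress_maxima(spine, result, list(type = "annulus",
                                           segment = seg))
    data.frame(scope = paste0("annulus:", seg), value = v$max_kpa,
               stringsAsFactors = FALSE)
  }))
  do.call(rbind, rows)
}

#' Write a comparison report as CSV, Markdown and JSON
#'
#' @param report a `comparison_report`.
#' @param base output path prefix.
#' @param meta named list embedded in the JSON twin (e.g. seed, config
#'   hash).
#' @return invisibly, the paths written.
#' @export
write_comparison_report <- function(report, base, meta = list()) {
  csv <- paste0(base, ".csv"); md <- paste0(base, ".md")
  js <- paste0(base, ".json")
  utils::write.csv(report, csv, row.names = FALSE)
  lines <- c("| Scope | Pre | Post | Percent | Times | Direction |",
             "|---|---|---|---|---|---|",
             sprintf("| %s | %.4g | %.4g | %s | %s | %s |",
                     report$scope, report$pre, report$post,
                     ifelse(is.na(report$percent), "-",
                            sprintf("%.1f%%", report$percent)),
                     ifelse(is.na(report$times), "-",
                            format(report$times)),
                     ifelse(is.na(report$direction), "-",
                            report$direction)))
  writeLines(lines, md)
  jsonlite::write_json(list(meta = meta, rows = report), js,
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(csv, md, js))
}

## tiny polynomial hash of a serialized R object (config provenance in
## reports; not cryptographic)
config_hash <- function(x) {
  bytes <- as.numeric(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
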