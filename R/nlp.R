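# Spanish clinical-note processing: normalisation, dictionary/regex
# criterion detection (V1 = dictionary only, V2 = dictionary plus
# context-window rules), severity scoring and agreement statistics.

idsa_criteria <- function() {
  c("invasive_ventilation", "septic_shock", "tachypnea", "pao2_fio2",
    "multilobar_opacities", "confusion", "uremia", "leukopenia",
    "hypotension")
}

#' Load a criterion dictionary
#'
#' Reads the YAML dictionary (criterion -> regex patterns, weight,
#' context rules) and validates that all nine IDSA/ATS criteria are
#' present and every pattern compiles.
#'
#' @param path YAML file; default is the dictionary shipped with the
#'   package (illustrative, not any study's production lexicon).
#' @return object of class `criterion_dictionary`.
#' @export
load_dictionary <- function(path = system.file("extdata",
                                               "idsa_dictionary.yaml",
                                               package = "pneumabio")) {
  d <- yaml::read_yaml(path)
  missing <- setdiff(idsa_criteria(), names(d$criteria))
  if (length(missing)) {
    pb_stop(paste("dictionary missing criteria:",
                  paste(missing, collapse = ", ")), "pb_config_error")
  }
  for (cr in names(d$criteria)) {
    for (p in d$criteria[[cr]]$patterns) {
      ok <- tryCatch({ grepl(p, "x", perl = TRUE); TRUE },
                     error = function(e) FALSE)
      if (!ok) pb_stop(sprintf("invalid regex in '%s': %s", cr, p),
                       "pb_config_error")
    }
  }
  structure(d, class = "criterion_dictionary")
}

# Diacritic folding table; n-tilde is preserved (semantic in Spanish).
fold_map <- function() {
  c("á" = "a", "é" = "e", "í" = "i", "ó" = "o",
    "ú" = "u", "ü" = "u", "Á" = "A", "É" = "E",
    "Í" = "I", "Ó" = "O", "Ú" = "U", "Ü" = "U",
    # unicode sub/superscript digits -> digits
    "₀" = "0", "₁" = "1", "₂" = "2", "₃" = "3",
    "₄" = "4", "₅" = "5", "₆" = "6", "₇" = "7",
    "₈" = "8", "₉" = "9")
}

#' Normalise Spanish clinical text
#'
#' Lowercases, folds diacritics (a-acute to a, etc.; n-tilde preserved),
#' maps unicode subscript digits to plain digits, and collapses
#' punctuation/whitespace runs to single spaces. An offset map links each
#' normalised character back to its position in the raw text, so matched
#' spans can be reported against the original note.
#'
#' @param text a single UTF-8 string.
#' @return list with `text` (normalised) and `offsets` (integer vector,
#'   original index of each normalised character).
#' @export
normalise_text <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text)) return(list(text = "", offsets = integer(0)))
  chars <- strsplit(text, "")[[1]]
  fm <- fold_map()
  out <- character(0); map <- integer(0)
  last_space <- TRUE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (!is.na(fm[ch])) ch <- unname(fm[ch])
    ch <- tolower(ch)
    keep <- grepl("[a-z0-9ñ/<>=.-]", ch)
    if (keep && ch == ".") keep <- FALSE      # sentence punctuation
    if (keep) {
      out <- c(out, ch); map <- c(map, i)
      last_space <- FALSE
    } else if (!last_space) {
      out <- c(out, " "); map <- c(map, i)
      last_space <- TRUE
    }
  }
  # trim trailing space
  while (length(out) && out[length(out)] == " ") {
    out <- out[-length(out)]; map <- map[-length(map)]
  }
  list(text = paste(out, collapse = ""), offsets = map)
}

match_one <- function(norm, crit_def, version) {
  spans <- list()
  detected <- FALSE
  for (p in crit_def$patterns) {
    m <- gregexpr(p, norm$text, perl = TRUE)[[1]]
    if (m[1] != -1L) {
      detected <- TRUE
      for (k in seq_along(m)) {
        s <- m[k]; e <- m[k] + attr(m, "match.length")[k] - 1L
        spans[[length(spans) + 1L]] <-
          c(start = norm$offsets[s], end = norm$offsets[e])
      }
    }
  }
  via <- if (detected) "V1" else NA_character_
  if (version == "V2" && !is.null(crit_def$context_rules)) {
    toks <- strsplit(norm$text, " +")[[1]]
    for (rule in crit_def$context_rules) {
      ai <- which(grepl(rule$anchor, toks, perl = TRUE))
      ci <- which(grepl(rule$companion, toks, perl = TRUE))
      if (length(ai) && length(ci) &&
          min(abs(outer(ai, ci, "-"))) <= rule$max_distance) {
        if (!detected) via <- "V2"
        detected <- TRUE
      }
    }
  }
  list(detected = detected, spans = spans, via = via)
}

#' Detect IDSA/ATS criteria in one note
#'
#' V1 detects a criterion iff any dictionary pattern matches the
#' normalised note. V2 additionally fires when a context rule's anchor
#' and companion patterns co-occur within the rule's token distance
#' (context rules only add recall, so V2 detections are a superset of
#' V1's). Without a lexical match no detection is possible: absent
#' keywords yield false negatives, never false positives.
#'
#' @param note raw UTF-8 note text.
#' @param dictionary a `criterion_dictionary`.
#' @param version `"V1"` or `"V2"`.
#' @return object of class `criterion_match_set`: per-criterion
#'   `detected` logical, matched spans, and matcher version.
#' @export
match_criteria <- function(note, dictionary = load_dictionary(),
                           version = c("V2", "V1")) {
  version <- match.arg(version)
  norm <- normalise_text(note)
  res <- lapply(idsa_criteria(), function(cr) {
    match_one(norm, dictionary$criteria[[cr]], version)
  })
  names(res) <- idsa_criteria()
  structure(list(
    detected = vapply(res, `[[`, TRUE, "detected"),
    spans = lapply(res, `[[`, "spans"),
    via = vapply(res, `[[`, "", "via"),
    version = version
  ), class = "criterion_match_set")
}

#' Aggregate a severity score from criterion detections
#'
#' Score = sum of detected-criterion weights plus an age component
#' (default +1 point at age >= 65). Weights and the age rule come from
#' the dictionary configuration.
#'
#' @param matches a `criterion_match_set` (or logical vector named by
#'   criterion).
#' @param age patient age in years.
#' @param dictionary dictionary supplying weights and the age rule.
#' @return numeric severity score.
#' @export
severity_score <- function(matches, age, dictionary = load_dictionary()) {
  if (inherits(matches, "criterion_match_set")) matches <- matches$detected
  if (!is.numeric(age) || length(age) != 1L || is.na(age) || age < 0) {
    pb_stop("age must be a non-negative number", "pb_input_error")
  }
  w <- vapply(idsa_criteria(),
              function(cr) dictionary$criteria[[cr]]$weight %||% 1, 0)
  ac <- dictionary$age_component %||% list(threshold = 65, points = 1)
  sum(w[matches[idsa_criteria()]]) +
    if (age >= ac$threshold) ac$points else 0
}

#' Score a corpus of notes
#'
#' @param notes character vector of raw notes.
#' @param ages numeric vector of ages (recycled).
#' @param dictionary a `criterion_dictionary`.
#' @param version matcher version.
#' @return data.frame: `note_id`, one logical column per criterion,
#'   `severity_score`.
#' @export
score_notes <- function(notes, ages = 0, dictionary = load_dictionary(),
                        version = c("V2", "V1")) {
  version <- match.arg(version)
  ages <- rep_len(ages, length(notes))
  rows <- lapply(seq_along(notes), function(i) {
    m <- match_criteria(notes[i], dictionary, version)
    df <- as.data.frame(as.list(m$detected))
    df$severity_score <- severity_score(m, ages[i], dictionary)
    df
  })
  out <- do.call(rbind, rows)
  cbind(data.frame(note_id = seq_along(notes)), out)
}

kappa_from_counts <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  po <- (tp + tn) / n
  pe <- ((tp + fn) / n) * ((tp + fp) / n) +
    ((fn + tn) / n) * ((fp + tn) / n)
  if (abs(1 - pe) < 1e-12) {
    return(list(kappa = NA_real_, se = NA_real_, po = po, pe = pe,
                status = "undefined"))
  }
  k <- (po - pe) / (1 - pe)
  se <- sqrt(po * (1 - po) / (n * (1 - pe)^2))   # Cohen (1960) large-sample SE
  list(kappa = k, se = se, po = po, pe = pe, status = "ok")
}

#' Agreement statistics against gold annotations
#'
#' Per-criterion confusion matrix (prediction vs gold), raw agreement,
#' and Cohen's kappa with asymptotic 95% CI (kappa +/- 1.96 SE, simple
#' large-sample SE). The overall kappa pools all criteria's labels.
#'
#' @param pred data.frame with a logical/0-1 column per criterion.
#' @param gold data.frame with matching columns, aligned by row.
#' @param criteria criterion columns to compare.
#' @return object of class `agreement_report`: `per_criterion`
#'   data.frame (TP, FP, FN, TN, agreement, kappa, CI) and `overall`
#'   pooled kappa.
#' @export
agreement_stats <- function(pred, gold, criteria = idsa_criteria()) {
  stopifnot(nrow(pred) == nrow(gold))
  rows <- lapply(criteria, function(cr) {
    p <- as.logical(pred[[cr]]); g <- as.logical(gold[[cr]])
    tp <- sum(p & g); fp <- sum(p & !g)
    fn <- sum(!p & g); tn <- sum(!p & !g)
    k <- kappa_from_counts(tp, fp, fn, tn)
    data.frame(criterion = cr, tp = tp, fp = fp, fn = fn, tn = tn,
               agreement = (tp + tn) / (tp + fp + fn + tn),
               kappa = k$kappa,
               kappa_lo = k$kappa - 1.96 * k$se,
               kappa_hi = k$kappa + 1.96 * k$se)
  })
  per <- do.call(rbind, rows)
  allp <- unlist(lapply(criteria, function(cr) as.logical(pred[[cr]])))
  allg <- unlist(lapply(criteria, function(cr) as.logical(gold[[cr]])))
  ko <- kappa_from_counts(sum(allp & allg), sum(allp & !allg),
                          sum(!allp & allg), sum(!allp & !allg))
  structure(list(per_criterion = per,
                 overall = list(kappa = ko$kappa, se = ko$se,
                                lo = ko$kappa - 1.96 * ko$se,
                                hi = ko$kappa + 1.96 * ko$se)),
            class = "agreement_report")
}
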