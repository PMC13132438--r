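# Synthetic Spanish clinical-note corpus with gold criterion labels.
# Plant phrases come from the same dictionary the scorer uses (single
# source of truth), so detection behaviour is fully determined by the
# planting choices: gold-negative criteria never receive dictionary
# tokens (structural zero-false-positive property), gold positives are
# deliberately omitted at rate `fn_plant_rate` (planted false
# negatives), and negated distractor phrases -- which DO contain the
# token and therefore produce false positives in a negation-blind
# matcher -- are inserted at rate `negation_rate`.

distractor_sentences <- function() {
  c("paciente ingresa por cuadro respiratorio agudo de varios dias de evolucion.",
    "se continua manejo antibiotico segun protocolo institucional.",
    "afebril durante el turno, tolera via oral.",
    "se solicitan paraclinicos de control para manana.",
    "familiares informados del estado clinico actual.",
    "continua en sala general con monitorizacion no invasiva.")
}

negation_templates <- function() {
  c("niega %s.", "sin evidencia de %s.", "no presenta %s.")
}

#' Generate a synthetic Spanish note corpus with gold labels
#'
#' @param n number of notes.
#' @param criterion_prevalence named numeric vector of gold prevalences
#'   in `[0,1]` (criteria absent from the vector get 0); a single
#'   unnamed value applies to all nine criteria.
#' @param fn_plant_rate probability that a gold-positive criterion's
#'   phrase is deliberately omitted (a planted false negative).
#' @param negation_rate probability that a gold-negative criterion
#'   contributes a negated distractor mentioning the dictionary phrase.
#' @param context_plant_rate probability that a planted positive uses a
#'   context-rule surface form (detectable by V2 only) instead of a
#'   plain dictionary phrase, for criteria that have context rules.
#' @param dictionary the `criterion_dictionary` supplying phrases.
#' @param seed RNG seed.
#' @return list with `notes` (character), `gold` (data.frame: note_id,
#'   age, per-criterion logical, gold_score), and `dictionary`.
#' @export
gen_notes_corpus <- function(n, criterion_prevalence = 0.3,
                             fn_plant_rate = 0, negation_rate = 0,
                             context_plant_rate = 0,
                             dictionary = load_dictionary(),
                             seed = 1L) {
  crits <- idsa_criteria()
  if (is.null(names(criterion_prevalence))) {
    prev <- stats::setNames(rep_len(criterion_prevalence, length(crits)),
                            crits)
  } else {
    prev <- stats::setNames(rep(0, length(crits)), crits)
    prev[names(criterion_prevalence)] <- criterion_prevalence
  }
  if (any(prev < 0 | prev > 1)) {
    pb_stop("prevalences must lie in [0,1]", "pb_input_error")
  }
  with_seed(seed, {
    notes <- character(n)
    gold <- matrix(FALSE, n, length(crits),
                   dimnames = list(NULL, crits))
    ages <- sample(35:95, n, replace = TRUE)
    for (i in seq_len(n)) {
      sent <- sample(distractor_sentences(),
                     sample(2:3, 1))
      sent <- c(sprintf("paciente de %d años valorado en piso.", ages[i]),
                sent)
      for (cr in crits) {
        pos <- stats::runif(1) < prev[cr]
        gold[i, cr] <- pos
        cdef <- dictionary$criteria[[cr]]
        if (pos) {
          if (stats::runif(1) >= fn_plant_rate) {
            use_ctx <- length(cdef$context_rules) > 0 &&
              stats::runif(1) < context_plant_rate
            phrase <- if (use_ctx) {
              rule <- cdef$context_rules[[sample(length(cdef$context_rules), 1)]]
              rule$plant
            } else {
              sample(unlist(cdef$plant), 1)
            }
            sent <- c(sent, paste0(phrase, "."))
          } # else: planted false negative (no token at all)
        } else if (negation_rate > 0 && stats::runif(1) < negation_rate) {
          tmpl <- sample(negation_templates(), 1)
          sent <- c(sent, sprintf(tmpl, sample(unlist(cdef$plant), 1)))
        }
      }
      notes[i] <- paste(sample(sent), collapse = " ")
    }
    w <- vapply(crits, function(cr) dictionary$criteria[[cr]]$weight %||% 1, 0)
    ac <- dictionary$age_component %||% list(threshold = 65, points = 1)
    gold_df <- cbind(
      data.frame(note_id = seq_len(n), age = ages),
      as.data.frame(gold)
    )
    gold_df$gold_score <- as.numeric(gold %*% w) +
      ifelse(ages >= ac$threshold, ac$points, 0)
    list(notes = notes, gold = gold_df, dictionary = dictionary)
  })
}
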