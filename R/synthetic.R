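# Vocabulary pools for the token-mixture document generator. Four pools:
# regulatory boilerplate (with a paired "European-style" variant used for
# agency style shifts), biomedical filler, explicit AI phrases (drawn from
# the default taxonomy), and contextual AI phrases deliberately absent from
# the taxonomy so keyword-method failure modes exist by construction.

.boilerplate_pool <- c(
  "agency", "notice", "federal", "register", "docket", "submission", "public",
  "comment", "meeting", "committee", "guidance", "document", "industry",
  "staff", "final", "draft", "effective", "section", "act", "program",
  "review", "process", "application", "sponsor", "holder", "annual",
  "report", "requirement", "procedure", "availability", "establishment",
  "registration", "listing", "fee", "schedule", "waiver", "exemption",
  "notification", "publication", "compliance", "policy", "framework",
  "oversight", "approval", "standard", "regulation", "regulatory",
  "enforcement", "statute", "amendment"
)

# Paired style-shifted counterparts (same length, aligned element-wise).
.boilerplate_shifted <- c(
  "authority", "communication", "union", "journal", "dossier", "variation",
  "stakeholder", "consultation", "plenary", "rapporteur", "reflection",
  "annex", "marketing", "secretariat", "adopted", "provisional", "binding",
  "article", "treaty", "workplan", "assessment", "pathway", "authorisation",
  "applicant", "titleholder", "periodic", "epar", "obligation", "modality",
  "accessibility", "site", "certification", "inventory", "charge",
  "timetable", "derogation", "exception", "circulation", "gazette",
  "conformity", "measure", "scheme", "supervision", "opinion", "norm",
  "provision", "legislative", "sanction", "decree", "revision"
)

.biomed_pool <- c(
  "drug", "patient", "clinical", "trial", "safety", "efficacy", "dose",
  "tablet", "injection", "therapy", "treatment", "disease", "adverse",
  "event", "risk", "benefit", "study", "endpoint", "enrollment", "placebo",
  "biomarker", "pharmacokinetics", "manufacturing", "quality", "batch",
  "sterile", "excipient", "formulation", "stability", "bioavailability",
  "toxicity", "indication", "contraindication", "label", "prescription",
  "pharmacy", "vaccine", "antibody", "protein", "molecule", "therapeutic",
  "biologic", "pharmaceutical", "diagnosis", "dosage", "pharmacovigilance",
  "surveillance", "inspection", "specification", "validation"
)

# Contextual AI phrasing: describes AI/ML systems without using any term in
# the default taxonomy (checked by test), so these documents are invisible
# to the keyword method but visible to reference similarity.
.contextual_pool <- c(
  "automated decision support", "computational prediction tool",
  "advanced analytics platform", "self adapting software",
  "in silico modelling", "digital twin simulation",
  "automated image recognition", "intelligent automation",
  "pattern recognition system", "automated signal detection",
  "computer assisted review", "adaptive software function",
  "model informed evaluation", "automated text mining",
  "statistical inference engine", "autonomous screening tool"
)

.language_default <- c(en = 0.95, fr = 0.03, de = 0.02)
.category_default <- c("guidance" = 0.50, "technical report" = 0.20,
                       "policy" = 0.12, "drug label" = 0.10,
                       "administrative notice" = 0.08)

#' Parameters for the synthetic corpus generator
#'
#' Defaults emulate the statistical structure of a large regulatory corpus:
#' about 3% AI-relevance prevalence, a 60/40 split of relevant documents
#' into explicit AI terminology versus contextual-only phrasing, an agency
#' mixture dominated by the largest regulator, and metadata (dates,
#' languages, categories) supporting funnel filtering. `style_shift` gives a
#' per-agency rate at which regulatory boilerplate vocabulary is swapped for
#' a "European-style" variant, emulating cross-agency stylistic drift.
#'
#' @param n_docs number of documents.
#' @param prevalence fraction of relevant documents (assigned exactly:
#'   `round(n_docs * prevalence)` documents are relevant).
#' @param frac_explicit fraction of relevant documents using explicit
#'   taxonomy terminology; the rest use contextual phrasing only.
#' @param agencies named mixture weights (must sum to 1).
#' @param style_shift named per-agency boilerplate substitution rates.
#' @param date_min,date_max publication-date window (a small fraction of
#'   documents falls before the window or has an unknown date).
#' @param languages,categories named metadata mixtures.
#' @param doc_length integer range (min, max) of tokens per document.
#' @param ai_frac range of the per-document fraction of AI-pool tokens in
#'   relevant documents (drawn uniformly, giving a continuum of scores).
#' @param stray_term_rate probability that an irrelevant document contains
#'   one stray explicit AI phrase (background noise).
#' @param seed integer RNG seed; the whole corpus is a pure function of the
#'   parameters.
#' @return an object of class `regfed_generator_params`.
#' @export
generator_params <- function(n_docs = 1000L, prevalence = 0.03,
                             frac_explicit = 0.6,
                             agencies = c(FDA = 0.72, EMA = 0.23, WHO = 0.05),
                             style_shift = c(FDA = 0, EMA = 0, WHO = 0),
                             date_min = "2019-01-01", date_max = "2025-07-31",
                             languages = .language_default,
                             categories = .category_default,
                             doc_length = c(120L, 240L),
                             ai_frac = c(0.15, 0.55),
                             stray_term_rate = 0.05,
                             seed = 42L) {
  stopifnot(n_docs >= 1, prevalence >= 0, prevalence < 1,
            frac_explicit >= 0, frac_explicit <= 1,
            abs(sum(agencies) - 1) < 1e-8, all(agencies >= 0),
            all(style_shift >= 0), all(style_shift <= 1),
            abs(sum(languages) - 1) < 1e-8, abs(sum(categories) - 1) < 1e-8,
            length(doc_length) == 2L, doc_length[1] <= doc_length[2],
            length(ai_frac) == 2L, ai_frac[1] <= ai_frac[2],
            stray_term_rate >= 0, stray_term_rate <= 1)
  if (!all(names(agencies) %in% names(style_shift)))
    stop("style_shift must name every agency", call. = FALSE)
  structure(list(n_docs = as.integer(n_docs), prevalence = prevalence,
                 frac_explicit = frac_explicit, agencies = agencies,
                 style_shift = style_shift,
                 date_min = as.Date(date_min), date_max = as.Date(date_max),
                 languages = languages, categories = categories,
                 doc_length = as.integer(doc_length), ai_frac = ai_frac,
                 stray_term_rate = stray_term_rate, seed = as.integer(seed)),
            class = "regfed_generator_params")
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# Zipf-ish sampling weights: mild frequency skew over a vocabulary pool.
.pool_weights <- function(pool) 1 / seq_along(pool)^0.7

# Synthesize one document's text from the token-mixture model.
.synth_text <- function(kind, n_tok, ai_frac, shift_rate, tax) {
  draw_tokens <- function(pool, n) {
    if (n <= 0) return(character(0))
    sample(pool, n, replace = TRUE, prob = .pool_weights(pool))
  }
  ai_units <- character(0)
  if (kind == "explicit" || kind == "implicit") {
    pool <- if (kind == "explicit") names(tax$ai_terms) else .contextual_pool
    budget <- round(ai_frac * n_tok)
    while (budget > 0) {
      ph <- sample(pool, 1L, prob = .pool_weights(pool))
      ai_units <- c(ai_units, ph)
      budget <- budget - length(strsplit(ph, " ", fixed = TRUE)[[1L]])
    }
  } else if (kind == "stray") {
    ai_units <- sample(names(tax$ai_terms), 1L)
  }
  n_ai <- sum(lengths(strsplit(ai_units, " ", fixed = TRUE)))
  n_rest <- max(0L, n_tok - n_ai)
  boiler_share <- stats::runif(1, 0.45, 0.65)
  nb <- round(boiler_share * n_rest)
  boiler <- draw_tokens(.boilerplate_pool, nb)
  if (shift_rate > 0 && nb > 0) {
    swap <- stats::runif(nb) < shift_rate
    boiler[swap] <- .boilerplate_shifted[match(boiler[swap], .boilerplate_pool)]
  }
  biomed <- draw_tokens(.biomed_pool, n_rest - nb)
  units <- c(ai_units, boiler, biomed)
  paste(sample(units), collapse = " ")
}

#' Generate a labeled synthetic corpus
#'
#' Documents are token mixtures over four vocabulary pools — regulatory
#' boilerplate, biomedical filler, explicit AI terms (overlapping the
#' taxonomy) and contextual AI phrases (absent from the taxonomy) — with
#' pool weights set by the truth label and the explicit/implicit
#' assignment. Exactly `round(n_docs * prevalence)` documents are relevant.
#' Fully deterministic given the parameter seed.
#'
#' @param params a [generator_params()].
#' @param tax taxonomy supplying the explicit AI phrase pool.
#' @return object of class `regfed_labeled_corpus`: list with `corpus` (a
#'   `regfed_corpus`), `truth` (data frame `doc_id`, `relevant`, `explicit`,
#'   `ai_frac`) and `params`.
#' @export
generate_corpus <- function(params = generator_params(),
                            tax = default_taxonomy()) {
  stopifnot(inherits(params, "regfed_generator_params"),
            inherits(tax, "regfed_taxonomy"))
  with_seed(params$seed, {
    n <- params$n_docs
    n_rel <- round(n * params$prevalence)
    rel_idx <- sort(sample.int(n, n_rel))
    relevant <- seq_len(n) %in% rel_idx
    n_exp <- round(n_rel * params$frac_explicit)
    explicit <- logical(n)
    if (n_rel > 0)
      explicit[rel_idx[sample.int(n_rel, n_exp)]] <- TRUE

    agency <- sample(names(params$agencies), n, replace = TRUE,
                     prob = params$agencies)
    shift <- params$style_shift[agency]
    language <- sample(names(params$languages), n, replace = TRUE,
                       prob = params$languages)
    category <- sample(names(params$categories), n, replace = TRUE,
                       prob = params$categories)
    span <- as.integer(params$date_max - params$date_min)
    date <- params$date_min + sample.int(span + 1L, n, replace = TRUE) - 1L
    early <- stats::runif(n) < 0.04           # a tail predating the window
    date[early] <- params$date_min - sample.int(900L, sum(early), replace = TRUE)
    date[stats::runif(n) < 0.02] <- NA        # unknown dates

    n_tok <- sample(seq(params$doc_length[1L], params$doc_length[2L]), n,
                    replace = TRUE)
    ai_frac <- ifelse(relevant,
                      stats::runif(n, params$ai_frac[1L], params$ai_frac[2L]), 0)
    stray <- !relevant & stats::runif(n) < params$stray_term_rate
    kind <- ifelse(relevant, ifelse(explicit, "explicit", "implicit"),
                   ifelse(stray, "stray", "irrelevant"))
    text <- vapply(seq_len(n), function(i)
      .synth_text(kind[i], n_tok[i], ai_frac[i], shift[i], tax), character(1))

    doc_id <- sprintf("doc-%05d", seq_len(n))
    cp <- corpus(data.frame(
      doc_id = doc_id, agency = agency,
      url = sprintf("https://example.org/%s/%s", tolower(agency), doc_id),
      title = paste("synthetic document", doc_id),
      date = date, language = language, category = category,
      text = text, stringsAsFactors = FALSE
    ), provenance = sprintf("synthetic corpus (n=%d, seed=%d)", n, params$seed))
    structure(list(corpus = cp,
                   truth = data.frame(doc_id = doc_id, relevant = relevant,
                                      explicit = explicit, ai_frac = ai_frac,
                                      stringsAsFactors = FALSE),
                   params = params),
              class = "regfed_labeled_corpus")
  })
}

#' @export
print.regfed_labeled_corpus <- function(x, ...) {
  cat(sprintf("<regfed_labeled_corpus> %d documents, %d relevant (%d explicit)\n",
              nrow(x$corpus), sum(x$truth$relevant),
              sum(x$truth$explicit)))
  invisible(x)
}

#' Generate exemplar reference documents
#'
#' Synthesizes relevant-style documents for use as a reference set: a mix of
#' explicit-terminology and contextual-phrasing exemplars, optionally in a
#' style-shifted agency's vocabulary (for bias-mitigation experiments).
#' Ids are prefixed so they can never collide with corpus documents.
#'
#' @param n number of exemplars.
#' @param frac_explicit fraction using explicit taxonomy terminology.
#' @param seed RNG seed.
#' @param style_shift boilerplate substitution rate for the exemplars.
#' @param tax taxonomy supplying the explicit phrase pool.
#' @param prefix id prefix.
#' @param agency agency tag recorded on the exemplars.
#' @return a `regfed_corpus` of `n` exemplar documents.
#' @export
generate_reference_docs <- function(n = 34L, frac_explicit = 0.5, seed = 7L,
                                    style_shift = 0, tax = default_taxonomy(),
                                    prefix = "ref", agency = "FDA") {
  with_seed(seed, {
    n_exp <- round(n * frac_explicit)
    kind <- c(rep("explicit", n_exp), rep("implicit", n - n_exp))
    text <- vapply(seq_len(n), function(i)
      .synth_text(kind[i], sample(120:200, 1L), stats::runif(1, 0.30, 0.50),
                  style_shift, tax), character(1))
    corpus(data.frame(
      doc_id = sprintf("%s-%03d", prefix, seq_len(n)), agency = agency,
      title = paste("reference exemplar", seq_len(n)),
      category = "reference", text = text, stringsAsFactors = FALSE
    ), provenance = sprintf("synthetic reference exemplars (n=%d, seed=%d)",
                            n, seed))
  })
}

#' Sample a labeled test set from a synthetic corpus
#'
#' Samples `n_relevant` relevant document ids and marks the `n_high` with
#' the highest explicit-AI token density as high-confidence (ties broken by
#' id). Reference-document disjointness is guaranteed by excluding any ids
#' passed in `exclude_ids`.
#'
#' @param lc a `regfed_labeled_corpus`.
#' @param n_relevant test-set size (default 127, the study shape).
#' @param n_high high-confidence subset size (default 38).
#' @param seed RNG seed.
#' @param exclude_ids ids that must not enter the test set.
#' @return a [test_set()].
#' @export
generate_test_set <- function(lc, n_relevant = 127L, n_high = 38L, seed = 1L,
                              exclude_ids = character(0)) {
  stopifnot(inherits(lc, "regfed_labeled_corpus"), n_high <= n_relevant)
  pool <- lc$truth[lc$truth$relevant & !(lc$truth$doc_id %in% exclude_ids), ]
  if (nrow(pool) < n_relevant)
    stop("not enough relevant documents: have ", nrow(pool), ", need ",
         n_relevant, call. = FALSE)
  with_seed(seed, {
    picked <- pool[sample.int(nrow(pool), n_relevant), ]
    dens <- ifelse(picked$explicit, picked$ai_frac, 0)
    ord <- order(-dens, picked$doc_id)
    high <- picked$doc_id[ord[seq_len(n_high)]]
    test_set(picked$doc_id, high)
  })
}

#' Generate a before/after snapshot pair with a known diff
#'
#' Builds two sitemap snapshots over a labeled corpus's URLs whose true diff
#' is known by construction: `n_new` documents appear only in the second
#' snapshot and `n_updated` carry a changed modification timestamp.
#'
#' @param lc a `regfed_labeled_corpus`.
#' @param n_new,n_updated counts of new and touched entries.
#' @param seed RNG seed.
#' @param source snapshot source label.
#' @return list: `old`, `new` (snapshots) and `expected` (the diff that
#'   [diff_snapshots()] must return).
#' @export
generate_snapshot_pair <- function(lc, n_new = 10L, n_updated = 10L, seed = 1L,
                                   source = "synthetic") {
  stopifnot(inherits(lc, "regfed_labeled_corpus"),
            n_new + n_updated <= nrow(lc$corpus))
  with_seed(seed, {
    urls <- lc$corpus$url
    n <- length(urls)
    pick <- sample.int(n, n_new + n_updated)
    new_idx <- pick[seq_len(n_new)]
    upd_idx <- pick[n_new + seq_len(n_updated)]
    t0 <- "2025-01-01T00:00:00"
    t1 <- "2025-02-01T00:00:00"
    old_urls <- if (length(new_idx)) urls[-new_idx] else urls
    old_entries <- data.frame(url = old_urls,
                              last_modified = t0, stringsAsFactors = FALSE)
    new_entries <- data.frame(url = urls, last_modified = t0,
                              stringsAsFactors = FALSE)
    new_entries$last_modified[new_entries$url %in% urls[c(new_idx, upd_idx)]] <- t1
    list(old = snapshot(old_entries, source = source, taken_at = t0),
         new = snapshot(new_entries, source = source, taken_at = t1),
         expected = list(new_urls = urls[new_idx],
                         updated_urls = urls[upd_idx],
                         removed_urls = character(0)))
  })
}

#' Contextual AI phrase pool used by the generator
#'
#' Exposed so tests can assert its deliberate disjointness from the default
#' taxonomy's AI terminology.
#'
#' @return character vector of contextual phrases.
#' @export
contextual_phrases <- function() .contextual_pool
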