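# Desk-scale analogue of the closed-loop intelligibility test: synthesize
# isolated pseudo-vowels from a simulated new speaker through the full
# calibration -> network -> MLSA cascade and identify them with the
# centroid classifier against anasynth templates of the reference corpus.

#' Closed-loop pseudo-vowel identification
#'
#' For every isolated-vowel item of the reference corpus, a class template
#' is built by synthesizing the item's true mel-cepstra with the fixed
#' template excitation and re-analyzing the audio (the anasynth condition,
#' the quality ceiling of the vocoder); per-class templates are the
#' steady-state cepstra averaged over items. Each new-speaker rendition is
#' then streamed through calibration, network and MLSA filter, re-analyzed
#' the same way, and classified by nearest mel-cepstral-distortion
#' centroid.
#'
#' @param corpus a `synth_corpus` (provides the vowel items and truth).
#' @param model a trained `dnn_model`.
#' @param calibration a `linear_calibration` mapping the new speaker into
#'   the reference space.
#' @param new_items items from [generate_new_speaker()] (`$items`).
#' @param template single-period excitation template.
#' @param hop,alpha vocoder settings.
#' @return List: `accuracy`, `chance`, `truth`, `predicted`, `confusion`
#'   (a [confusion_matrix] over the vowel classes present).
#' @export
closed_loop_vowel_eval <- function(corpus, model, calibration, new_items,
                                   template, hop = 220, alpha = 0.455) {
  vowel_idx <- which(vapply(corpus$items, function(i) i$type, "") == "vowel")
  if (length(vowel_idx) == 0) stop("corpus has no isolated-vowel items")
  steady_cep <- function(wave, seg) {
    cep <- analyze_mel_cepstrum(wave, alpha = alpha, hop = hop)
    ss <- phone_frame_indices(seg, rate = 100)[[1]]$frames
    ss <- ss[ss <= nrow(cep$frames)]
    cep$frames[ss, , drop = FALSE]
  }
  templates <- list()
  truth <- character(0)
  stimuli <- list()
  for (k in vowel_idx) {
    item <- corpus$items[[k]]
    lab <- item$transcript[1]
    Tn <- nrow(item$melcep$frames)
    exc <- build_template_excitation(template, 22050, Tn * hop)
    ref_wave <- mlsa_synthesize(exc, item$melcep)
    templates[[lab]] <- rbind(templates[[lab]],
                              steady_cep(ref_wave, item$seg))
    new_wave <- synthesize_offline(new_items[[k]]$artic100, model, template,
                                   calibration = calibration, hop = hop,
                                   alpha = alpha)
    stimuli[[length(stimuli) + 1]] <- steady_cep(new_wave, item$seg)
    truth <- c(truth, lab)
  }
  predicted <- centroid_classify(stimuli, templates)
  labs <- sort(unique(truth))
  list(accuracy = accuracy(truth, predicted),
       chance = chance_level(length(labs)),
       truth = truth, predicted = predicted,
       confusion = confusion_matrix(truth, predicted, labs))
}
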