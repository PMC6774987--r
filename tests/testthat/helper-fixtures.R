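# Small in-code fixtures shared across test files.

phrase_row <- function(singer_id, phrase_index, phrase_type, units,
                       location = substr(singer_id, 1, 2),
                       recording = 1L) {
  data.frame(singer_id = singer_id, location = location,
             recording = recording, phrase_index = phrase_index,
             phrase_type = phrase_type,
             theme = as.integer(sub("[A-Za-z]$", "", phrase_type)),
             units = units, stringsAsFactors = FALSE)
}

# Two grounds (NC, TO) plus two stopover singers; NC carries a private
# variant (1B) of theme 1, TO the base phrase (1A); theme 2 is shared.
make_test_corpora <- function() {
  grounds <- song_corpus(rbind(
    phrase_row("NC01S1", 1, "1B", "a b x"),
    phrase_row("NC01S1", 2, "1B", "a b x"),
    phrase_row("NC01S1", 3, "2A", "c d e"),
    phrase_row("NC02S1", 1, "1B", "a b x"),
    phrase_row("NC02S1", 2, "2A", "c d e"),
    phrase_row("TO01S1", 1, "1A", "a b c"),
    phrase_row("TO01S1", 2, "2A", "c d e"),
    phrase_row("TO02S1", 1, "1A", "a b c"),
    phrase_row("TO02S1", 2, "2A", "c d e")))
  stopover <- song_corpus(rbind(
    phrase_row("KI01S1", 1, "1B", "a b x"),
    phrase_row("KI01S1", 2, "2A", "c d e"),
    phrase_row("KI02S1", 1, "1A", "a b c"),
    phrase_row("KI02S1", 2, "2A", "c d e")))
  list(grounds = grounds, stopover = stopover)
}

# A feature table with hand-set centroids for labels; one exemplar per label
# unless `reps` is larger (exemplars then identical).
feature_table_from_centroids <- function(centroids, reps = 1L) {
  rows <- do.call(rbind, lapply(rownames(centroids), function(lab) {
    row <- as.data.frame(as.list(centroids[lab, ]))
    row <- row[rep(1L, reps), , drop = FALSE]
    row$unit_label <- lab
    row
  }))
  unit_feature_table(rows)
}

# Valid 11-feature centroid rows built from a few free parameters, so tests
# can place labels in feature space without violating table invariants.
make_centroid <- function(dur, fmin, fmax, peak = (fmin + fmax) / 2,
                          sf = fmin, ef = fmax, infl = 0, pulse = 0) {
  c(duration_s = dur, min_freq_hz = fmin, max_freq_hz = fmax,
    bandwidth_hz = fmax - fmin, peak_freq_hz = peak, start_freq_hz = sf,
    end_freq_hz = ef, freq_trend_ratio = sf / ef,
    freq_range_ratio = fmin / fmax, n_inflections = infl,
    pulse_rate_hz = pulse)
}
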