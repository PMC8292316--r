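# Build a sleep-event row for the night of `night` (a Date): onset_h is a
# clock hour; values >= 12 are taken on the night's own evening, values
# below 12 in the small hours of the following morning (negative values are
# hours before that midnight). Duration in minutes of time in bed; minutes
# asleep defaults to the full span.
make_event <- function(subject_id, night, onset_h, dur_min,
                       asleep = dur_min) {
  night <- as.Date(night)
  if (onset_h >= 12) onset_h <- onset_h - 24
  midnight_next <- as.POSIXct(paste(night + 1, "00:00:00"), tz = "UTC")
  start <- midnight_next + onset_h * 3600
  data.frame(subject_id = subject_id, start = start,
             end = start + dur_min * 60,
             minutes_asleep = asleep, minutes_in_bed = dur_min,
             stringsAsFactors = FALSE)
}

make_events <- function(...) do.call(rbind, list(...))

# A minimal complete genotype set: dosage matrix given explicitly, effect
# sizes supplied, all variants autosomal and common unless overridden.
make_genotypes <- function(dosages, effect_size,
                           chrom = rep("1", ncol(dosages)),
                           pos = seq_len(ncol(dosages)) * 1e6) {
  m <- ncol(dosages)
  subjects <- sprintf("S%02d", seq_len(nrow(dosages)))
  af <- colSums(dosages, na.rm = TRUE) /
    (2 * colSums(!is.na(dosages)))
  variants <- data.frame(
    variant_id = sprintf("v%03d", seq_len(m)),
    chrom = chrom, pos = pos,
    effect_allele = "A", other_allele = "G",
    effect_size = effect_size, maf = pmin(af, 1 - af),
    stringsAsFactors = FALSE)
  genotype_set(dosages, variants, subjects)
}

DST19 <- as.Date("2019-03-10")
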