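# Minimal 16-bit EDF writer used only to exercise the reader round-trip;
# the file is created programmatically at test time.
write_edf <- function(path, data, rate, labels,
                      phys_range = c(-200, 200)) {
  ns <- nrow(data)
  record_dur <- 1
  spr <- as.integer(rate * record_dur)
  n_records <- ncol(data) %/% spr
  pad <- function(x, width) formatC(as.character(x), width = width,
                                    flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad("test subject", 80), pad("test recording", 80),
    pad("01.01.26", 8), pad("00.00.00", 8),
    pad(256 + 256 * ns, 8), pad("", 44),
    pad(n_records, 8), pad(record_dur, 8), pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  field <- function(values, width) {
    paste0(vapply(values, pad, character(1), width = width), collapse = "")
  }
  dig_range <- c(-32768, 32767)
  sig <- paste0(
    field(labels, 16), field(rep("AgAgCl", ns), 80),
    field(rep("uV", ns), 8),
    field(rep(phys_range[1], ns), 8), field(rep(phys_range[2], ns), 8),
    field(rep(dig_range[1], ns), 8), field(rep(dig_range[2], ns), 8),
    field(rep("", ns), 80), field(rep(spr, ns), 8), field(rep("", ns), 32)
  )
  writeChar(sig, con, eos = NULL)
  gain <- (dig_range[2] - dig_range[1]) / (phys_range[2] - phys_range[1])
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      seg <- data[s, ((r - 1) * spr + 1):(r * spr)]
      dig <- as.integer(round((seg - phys_range[1]) * gain + dig_range[1]))
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}
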