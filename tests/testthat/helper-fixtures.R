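# Shared fixtures, built in code at test time.

ts_proteins <- function() {
  tibble::tibble(
    accession = paste0("P", 1:5),
    description = paste("synthetic protein", 1:5),
    sequence = c(
      "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQAPILSRVGDGTQDNLSGAEKAVQVKVK",
      "MSDNNTIFARITGESLEDLKNRLAEAGISSTQLMERAGQSLADELRKDPNVSAVLVGSGK",
      "MALWMRLLPLLALLALWGPDPAAAFVNQHLCGSHLVEALYLVCGERGFFYTPKTRREAED",
      "MGDVEKGKKIFIMKCSQCHTVEKGGKHKTGPNLHGLFGRKTGQAPGYSYTAANKNKGIIW",
      "MTEYKLVVVGAGGVGKSALTIQLIQNHFVDEYDPTIEDSYRKQVVIDGETCLLDILDTAG"
    )
  )
}

# low-homology foreign proteins for entrapment runs
ts_entrapment_proteins <- function() {
  tibble::tibble(
    accession = paste0("ENT", 1:4),
    description = "synthetic entrapment protein",
    sequence = c(
      "MHHLEPWGNDTLAYFQCVIPGMTNDWESHVLTPFGERAWQICNGDYLHPTFAVESWIDGK",
      "MWDNPEAHTLFYGICQVRSGDMTWLNEHPAVFKGICESYDWQNHPLTAGRVFMEDICWSK",
      "MFGHWDNECPATLVYQIGSRMEWDLHNPTFCAVGKEIWSYDQCHNPLGTRAFVMDEIWCK",
      "MYHWGDNPECATLFQVIRSGEMWDLTHNPAFCVKGEIWYSDQHCNPGLTARFVDMEICWK"
    )
  )
}

# brute-force digestion oracle: enumerate all substrings, classify termini
ts_digest_oracle <- function(sequence, max_missed, len_range,
                             specificity = "full") {
  n <- nchar(sequence)
  res <- strsplit(sequence, NULL)[[1]]
  cut <- which(res %in% c("K", "R"))
  cut <- cut[cut < n]
  enz_start <- function(st) st == 1L || (st - 1L) %in% cut ||
    (st == 2L && res[1] == "M")
  enz_end <- function(en) en == n || en %in% cut
  out <- character(0)
  for (st in seq_len(n)) {
    for (en in st:n) {
      len <- en - st + 1L
      if (len < len_range[1] || len > len_range[2]) next
      mc <- sum(cut >= st & cut < en)
      ok <- switch(specificity,
        full = enz_start(st) && enz_end(en) && mc <= max_missed,
        semi = enz_start(st) || enz_end(en),
        none = TRUE
      )
      if (ok) out <- c(out, substr(sequence, st, en))
    }
  }
  sort(unique(out))
}

# exhaustive upper-tail hypergeometric oracle by enumeration of draws
ts_hyper_tail_oracle <- function(x, K, N, k) {
  if (x <= 0) return(1)
  js <- x:min(K, k)
  js <- js[k - js <= N - K]
  if (!length(js)) return(0)
  sum(choose(K, js) * choose(N - K, k - js)) / choose(N, k)
}

# exact minimum set cover by subset enumeration
ts_min_cover_size <- function(sets) {
  universe <- unique(unlist(sets))
  n <- length(sets)
  for (size in seq_len(n)) {
    for (idx in utils::combn(n, size, simplify = FALSE)) {
      if (setequal(intersect(unique(unlist(sets[idx])), universe), universe)) {
        return(size)
      }
    }
  }
  n
}

ts_write_mgf_text <- function(path, blocks) {
  writeLines(unlist(blocks), path)
  path
}
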