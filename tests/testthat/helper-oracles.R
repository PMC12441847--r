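# independent textbook Welch oracle: scipy.signal.welch on the same samples,
# exchanged through full-precision text files
scipy_welch <- function(x, fs, nperseg, noverlap, window, detrend) {
  inf <- tempfile(fileext = ".txt")
  outf <- tempfile(fileext = ".txt")
  pyf <- tempfile(fileext = ".py")
  on.exit(unlink(c(inf, outf, pyf)))
  writeLines(formatC(x, format = "g", digits = 17), inf)
  writeLines(c(
    "import sys",
    "import numpy as np",
    "from scipy.signal import welch",
    "x = np.loadtxt(sys.argv[1])",
    sprintf("f, p = welch(x, fs=%.17g, nperseg=%d, noverlap=%d,", fs,
            nperseg, noverlap),
    sprintf("          window='%s', detrend=%s, scaling='density')", window,
            if (detrend == "none") "False" else "'constant'"),
    "np.savetxt(sys.argv[2], p, fmt='%.17g')"
  ), pyf)
  system2("python", c(pyf, inf, outf), stdout = TRUE, stderr = TRUE)
  as.numeric(readLines(outf))
}
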