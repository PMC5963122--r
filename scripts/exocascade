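#!/usr/bin/env Rscript
# Repository-level launcher: exocascade <run|simulate|evaluate|report> [...]
# Requires the package to be installed (R CMD INSTALL .).
quit(status = exocascade::exo_main(commandArgs(trailingOnly = TRUE)),
     save = "no")
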