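#!/usr/bin/env Rscript
# Stage 4: hold-out validation of the M1 fit.
#
# Plug-in predictions on the 40% hold-out split, binarised at the 0.65
# cut-off; confusion matrix, sensitivity/specificity/accuracy and the ROC
# curve with its AUC. For reference the published worked example is also
# recomputed from its printed confusion counts.

suppressPackageStartupMessages(library(fevertreat))

fits <- readRDS("results/fits.rds")
validation <- utils::read.csv("results/validation.csv")
pm <- posterior_means(fits[["M1"]])

probs <- predict_treatment(validation,
                           item_parameters(pm[["a"]], pm[["b"]], pm[["c"]]),
                           trait_model("M1", alpha = pm[["alpha"]],
                                       beta = pm[["beta"]]))
cm <- classify(probs, validation$y, cutoff = 0.65)
mets <- metrics(cm)
rc <- roc(probs, validation$y)
print(cm)
cat(sprintf("Synthetic hold-out: sensitivity %.3f, specificity %.3f, accuracy %.3f, AUC %.3f\n",
            mets$sensitivity, mets$specificity, mets$accuracy, rc$auc))

utils::write.csv(data.frame(tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
                            sensitivity = mets$sensitivity,
                            specificity = mets$specificity,
                            accuracy = mets$accuracy, auc = rc$auc),
                 "results/validation_metrics.csv", row.names = FALSE)
utils::write.csv(rc$curve, "results/roc_curve.csv", row.names = FALSE)

# the published worked example, from its printed counts
pub <- metrics(confusion_matrix(tp = 155, fp = 21, tn = 64, fn = 7))
cat(sprintf("Published matrix recomputed: specificity %.1f%%, accuracy %.3f (matrix-implied sensitivity %.1f%%)\n",
            100 * pub$specificity, pub$accuracy, 100 * pub$sensitivity))
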