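method,dataset,accuracy
LSNet,Accuracy,92.50
LSNet,Precision,93.38
LSNet,F1-score,92.48
FedAvg+SwinUnet,Accuracy,97.40
FedAvg+SwinUnet,Precision,97.47
FedAvg+SwinUnet,F1-score,97.40
FL-LSNet,Accuracy,98.65
FL-LSNet,Precision,98.68
FL-LSNet,F1-score,98.65
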