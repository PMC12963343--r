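method,dataset,accuracy
FedAvg,CCMT,80.39
FedAvg,Taiwan,79.86
FedAvg,PlantVillage,97.40
FedProx,CCMT,81.25
FedProx,Taiwan,80.43
FedProx,PlantVillage,97.85
MOON,CCMT,82.55
MOON,Taiwan,79.36
MOON,PlantVillage,98.65
FL-LSNet,CCMT,84.32
FL-LSNet,Taiwan,85.14
FL-LSNet,PlantVillage,98.92
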