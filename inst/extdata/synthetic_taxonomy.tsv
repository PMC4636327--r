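Strain01_ref	Bacteria;Synthphylum1;Synthclass1;Synthorder1;Synthfamily1;Synthgenus01;
Strain02_ref	Bacteria;Synthphylum1;Synthclass1;Synthorder1;Synthfamily1;Synthgenus02;
Strain03_ref	Bacteria;Synthphylum1;Synthclass1;Synthorder1;Synthfamily1;Synthgenus03;
Strain04_ref	Bacteria;Synthphylum2;Synthclass2;Synthorder2;Synthfamily2;Synthgenus04;
Strain05_ref	Bacteria;Synthphylum2;Synthclass2;Synthorder2;Synthfamily2;Synthgenus05;
Strain06_ref	Bacteria;Synthphylum2;Synthclass2;Synthorder2;Synthfamily2;Synthgenus06;
Strain07_ref	Bacteria;Synthphylum3;Synthclass3;Synthorder3;Synthfamily3;Synthgenus07;
Strain08_ref	Bacteria;Synthphylum3;Synthclass3;Synthorder3;Synthfamily3;Synthgenus08;
Strain09_ref	Bacteria;Synthphylum3;Synthclass3;Synthorder3;Synthfamily3;Synthgenus09;
Strain10_ref	Bacteria;Synthphylum4;Synthclass4;Synthorder4;Synthfamily4;Synthgenus10;
Strain11_ref	Bacteria;Synthphylum4;Synthclass4;Synthorder4;Synthfamily4;Synthgenus11;
Strain12_ref	Bacteria;Synthphylum4;Synthclass4;Synthorder4;Synthfamily4;Synthgenus12;
Strain13_ref	Bacteria;Synthphylum5;Synthclass5;Synthorder5;Synthfamily5;Synthgenus13;
Strain14_ref	Bacteria;Synthphylum5;Synthclass5;Synthorder5;Synthfamily5;Synthgenus14;
Contam01_ref	Bacteria;Contphylum1;Contclass1;Contorder1;Contfamily1;Contgenus01;
Contam02_ref	Bacteria;Contphylum2;Contclass2;Contorder2;Contfamily2;Contgenus02;
Contam03_ref	Bacteria;Contphylum3;Contclass3;Contorder3;Contfamily3;Contgenus03;
Contam04_ref	Bacteria;Contphylum4;Contclass4;Contorder4;Contfamily4;Contgenus04;
Contam05_ref	Bacteria;Contphylum5;Contclass5;Contorder5;Contfamily5;Contgenus05;
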