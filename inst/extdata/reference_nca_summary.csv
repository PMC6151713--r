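analyte,parameter,phase,group,mean,sd,n
tegafur,t_half,single,control,2.3,0.7,5
tegafur,t_half,single,sdt,3.5,0.7,5
tegafur,tmax,single,control,1.5,0.4,5
tegafur,tmax,single,sdt,1.3,0.4,5
tegafur,cmax,single,control,9328.0,3099.3,5
tegafur,cmax,single,sdt,7202.0,2374.7,5
tegafur,auc_all,single,control,55372.7,20215.9,5
tegafur,auc_all,single,sdt,42705.1,11087.4,5
tegafur,auc_inf,single,control,55712.7,20247.5,5
tegafur,auc_inf,single,sdt,42945.5,11033.1,5
tegafur,cl_f,single,control,1.7,0.8,5
tegafur,cl_f,single,sdt,2.1,0.6,5
tegafur,vz_f,single,control,0.3,0.1,5
tegafur,vz_f,single,sdt,0.6,0.2,5
tegafur,t_half,multiple,control,2.2,1.4,5
tegafur,t_half,multiple,sdt,3.3,0.8,5
tegafur,tmax,multiple,control,1.2,0.7,5
tegafur,tmax,multiple,sdt,3.2,1.6,5
tegafur,cmax,multiple,control,6828.0,384.0,5
tegafur,cmax,multiple,sdt,4960.0,431.9,5
tegafur,auc_all,multiple,control,43496.9,4673.0,5
tegafur,auc_all,multiple,sdt,46842.4,8127.5,5
tegafur,auc_inf,multiple,control,43748.1,4835.6,5
tegafur,auc_inf,multiple,sdt,47461.3,8163.9,5
tegafur,cl_f,multiple,control,1.9,0.2,5
tegafur,cl_f,multiple,sdt,1.8,0.3,5
tegafur,vz_f,multiple,control,0.4,0.2,5
tegafur,vz_f,multiple,sdt,0.5,0.1,5
fu,t_half,single,control,2.6,2.1,5
fu,t_half,single,sdt,2.2,1.0,5
fu,tmax,single,control,1.7,0.8,5
fu,tmax,single,sdt,1.7,1.1,5
fu,cmax,single,control,178.2,42.0,5
fu,cmax,single,sdt,209.5,94.9,5
fu,auc_all,single,control,613.7,233.4,5
fu,auc_all,single,sdt,892.4,439.7,5
fu,auc_inf,single,control,924.9,537.6,5
fu,auc_inf,single,sdt,955.8,438.9,5
fu,auc_ratio_pct,single,control,2.5,0.9,5
fu,auc_ratio_pct,single,sdt,3.3,1.0,5
fu,t_half,multiple,control,3.0,0.9,5
fu,t_half,multiple,sdt,3.1,0.8,5
fu,tmax,multiple,control,1.8,0.3,5
fu,tmax,multiple,sdt,2.4,0.5,5
fu,cmax,multiple,control,172.2,40.4,5
fu,cmax,multiple,sdt,64.3,23.0,5
fu,auc_all,multiple,control,639.3,190,5
fu,auc_all,multiple,sdt,362.7,96.2,5
fu,auc_inf,multiple,control,750.2,145.8,5
fu,auc_inf,multiple,sdt,429.6,83.2,5
fu,auc_ratio_pct,multiple,control,2.7,0.7,5
fu,auc_ratio_pct,multiple,sdt,1.5,0.5,5
gimeracil,t_half,single,control,1.2,0.2,5
gimeracil,t_half,single,sdt,0.9,0.3,5
gimeracil,tmax,single,control,0.6,0.4,5
gimeracil,tmax,single,sdt,0.8,0.8,5
gimeracil,cmax,single,control,422.2,136.5,5
gimeracil,cmax,single,sdt,358,121.4,5
gimeracil,auc_all,single,control,768.3,312.9,5
gimeracil,auc_all,single,sdt,678.7,190.9,5
gimeracil,auc_inf,single,control,984.8,335.4,5
gimeracil,auc_inf,single,sdt,758.7,186.7,5
gimeracil,cl_f,single,control,26.8,8.8,5
gimeracil,cl_f,single,sdt,33.7,9.4,5
gimeracil,vz_f,single,control,2.9,1.3,5
gimeracil,vz_f,single,sdt,2.6,1.4,5
gimeracil,t_half,multiple,control,0.7,0.1,5
gimeracil,t_half,multiple,sdt,0.8,0.2,5
gimeracil,tmax,multiple,control,0.5,0.0,5
gimeracil,tmax,multiple,sdt,0.7,0.5,5
gimeracil,cmax,multiple,control,347.8,42.7,5
gimeracil,cmax,multiple,sdt,142.3,41.8,5
gimeracil,auc_all,multiple,control,449.5,74.2,5
gimeracil,auc_all,multiple,sdt,180.2,41.5,5
gimeracil,auc_inf,multiple,control,526.6,85.4,5
gimeracil,auc_inf,multiple,sdt,247.4,57.4,5
gimeracil,cl_f,multiple,control,46.9,7.8,5
gimeracil,cl_f,multiple,sdt,101.9,22.6,5
gimeracil,vz_f,multiple,control,2.8,0.4,5
gimeracil,vz_f,multiple,sdt,6.8,0.9,5
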